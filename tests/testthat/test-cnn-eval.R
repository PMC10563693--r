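test_that("confusion metrics follow the closed-form definitions", {
  m <- confusion_metrics(19, TN = 33, FP = 0, FN = 0)
  expect_equal(unlist(m[c("acc", "sen", "spe", "eff")]), c(
    acc = 1, sen = 1, spe = 1, eff = 1))

  m2 <- confusion_metrics(25, TN = 25, FP = 25, FN = 25)
  expect_equal(unlist(m2[c("acc", "sen", "spe", "eff")]), c(
    acc = 0.5, sen = 0.5, spe = 0.5, eff = 0.25))

  m3 <- confusion_metrics(0, TN = 10, FP = 0, FN = 10)
  expect_equal(unlist(m3[c("acc", "sen", "spe", "eff")]), c(
    acc = 0.5, sen = 0, spe = 1, eff = 0))

  expect_error(confusion_metrics(0, TN = 5, FP = 0, FN = 0),
               class = "mircos_metric_error")
  expect_error(confusion_metrics(5, TN = 0, FP = 0, FN = 0),
               class = "mircos_metric_error")
})

test_that("effectivity is the product of sensitivity and specificity", {
  set.seed(41)
  for (i in 1:20) {
    cts <- as.list(rpois(4, 10) + 1)
    names(cts) <- c("TP", "TN", "FP", "FN")
    m <- confusion_metrics(cts$TP, cts$TN, cts$FP, cts$FN)
    expect_identical(m$eff, m$sen * m$spe)
    # accuracy is invariant under class relabeling (TP<->TN, FP<->FN)
    m_sw <- confusion_metrics(cts$TN, cts$TP, cts$FN, cts$FP)
    expect_equal(m$acc, m_sw$acc)
  }
})

test_that("a majority-class predictor on a 33/19 role scores 33/52", {
  truth <- rep(c("cultivated", "wild"), c(33, 19))
  counts <- confusion_counts(truth, rep("cultivated", 52))
  m <- confusion_metrics(counts)
  expect_equal(m$acc, 33 / 52)
  expect_equal(round(100 * m$acc, 2), 63.46)
})

test_that("confusion counting uses wild as the positive class", {
  truth <- c("wild", "wild", "cultivated", "cultivated")
  pred <- c("wild", "cultivated", "cultivated", "wild")
  cts <- confusion_counts(truth, pred)
  expect_equal(unlist(cts[c("TP", "TN", "FP", "FN")]),
               c(TP = 1, TN = 1, FP = 1, FN = 1))
})

test_that("convolution gradients match finite differences", {
  set.seed(43)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  r <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))  # stride-2 output shape
  loss <- function(x, w, b) sum(mircos:::conv2d_forward(x, w, b, 2L, 1L) * r)
  g <- mircos:::conv2d_backward(x, w, r, 2L, 1L)
  eps <- 1e-6
  for (idx in sample(length(w), 5)) {
    wp <- w; wp[idx] <- wp[idx] + eps
    wm <- w; wm[idx] <- wm[idx] - eps
    expect_equal(g$dw[idx], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (idx in sample(length(x), 5)) {
    xp <- x; xp[idx] <- xp[idx] + eps
    xm <- x; xm[idx] <- xm[idx] - eps
    expect_equal(g$dx[idx], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  bp <- b; bp[2] <- bp[2] + eps
  bm <- b; bm[2] <- bm[2] - eps
  expect_equal(g$db[2], (loss(x, w, bp) - loss(x, w, bm)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("one epoch on a tiny dataset yields a finite single-row history", {
  ds <- tiny_dataset()
  mod <- train_classifier(ds, epochs = 1, seed = 2,
                          arch = resnet_spec(8, 1), batch_size = 4)
  expect_equal(nrow(mod$history), 1)
  expect_true(is.finite(mod$history$loss))
  expect_true(mod$history$acc_train >= 0 && mod$history$acc_train <= 1)
})

test_that("training is deterministic given the seed", {
  ds <- tiny_dataset()
  m1 <- train_classifier(ds, epochs = 2, seed = 5, arch = resnet_spec(8, 1),
                         batch_size = 4)
  m2 <- train_classifier(ds, epochs = 2, seed = 5, arch = resnet_spec(8, 1),
                         batch_size = 4)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  m3 <- train_classifier(ds, epochs = 2, seed = 6, arch = resnet_spec(8, 1),
                         batch_size = 4)
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("evaluation refuses external-validation roles that leak ids", {
  ds <- tiny_dataset()
  mod <- train_classifier(ds, epochs = 1, seed = 2, arch = resnet_spec(8, 1),
                          batch_size = 4)
  leaky <- ds
  bad_id <- leaky$manifest$sample_id[leaky$manifest$role == "train"][1]
  leaky$manifest$role[leaky$manifest$sample_id == bad_id] <- "ev"
  # the id now appears under ev in this manifest, but the model's dataset
  # still lists it as train elsewhere; rebuild a manifest with both roles
  extra <- ds$manifest[ds$manifest$sample_id == bad_id, ]
  extra$role <- "ev"
  leaky$manifest <- rbind(ds$manifest, extra)
  expect_error(evaluate_classifier(mod, leaky, "ev"),
               class = "mircos_leakage_error")
})

test_that("evaluation reports counts, metrics and loss coherently", {
  ds <- tiny_dataset()
  mod <- train_classifier(ds, epochs = 2, seed = 2, arch = resnet_spec(8, 1),
                          batch_size = 4)
  ev <- evaluate_classifier(mod, ds, "ev")
  total <- with(ev$counts, TP + TN + FP + FN)
  expect_equal(total, 5)
  expect_equal(ev$metrics$acc,
               with(ev$counts, (TP + TN) / total))
  expect_true(is.finite(ev$loss) && ev$loss > 0)
  expect_length(ev$predictions, 5)
})
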