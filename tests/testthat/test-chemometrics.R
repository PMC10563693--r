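test_that("PCA ratios behave as variance fractions with exact reconstruction", {
  # collinear points: all variance on the first axis
  X <- cbind(1:6, 2 * (1:6))
  p <- pca_fit(X, k = 2)
  expect_equal(p$explained_variance_ratio, c(1, 0), tolerance = 1e-12)

  set.seed(5)
  X <- matrix(rnorm(12 * 7), 12, 7)
  p <- pca_fit(X, k = 7)
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  Xc <- scale(X, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), unclass(Xc), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(crossprod(p$loadings), diag(7), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit(X, k = 12), class = "mircos_parameter_error")
})

test_that("PLS-DA separates well-separated clusters with one component", {
  d <- two_clusters()
  fit <- plsda_fit(d$X, d$y, n_components = 1, cv_folds = 5)
  expect_equal(fit$metrics$acc_train, 1)
  expect_gt(fit$metrics$Q2, 0.5)
  expect_lte(fit$metrics$Q2, fit$metrics$R2Y + 1e-9)
})

test_that("pure-noise labels give nonpositive Q2 in expectation", {
  q2 <- vapply(1:6, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 30), 60, 30)
    y <- rep(c("wild", "cultivated"), 30)
    plsda_fit(X, y, n_components = 2, cv_folds = 7)$metrics$Q2
  }, 0)
  expect_lt(mean(q2), 0)
})

test_that("training metrics are internally consistent", {
  d <- two_clusters(n_per = 15, gap = 3)
  fit <- plsda_fit(d$X, d$y, n_components = 2, cv_folds = 5)
  expect_equal(fit$metrics$RMSEE, sqrt(mean(fit$residuals^2)),
               tolerance = 1e-12)
  # evaluating on the training data itself: RMSEP == RMSEE
  ev <- plsda_evaluate(fit, d$X, d$y)
  expect_equal(ev$RMSEP, fit$metrics$RMSEE, tolerance = 1e-12)
  expect_lte(fit$metrics$Q2, fit$metrics$R2Y + 1e-9)
})

test_that("accuracy complements under label flipping", {
  d <- two_clusters(n_per = 12, gap = 5)
  fit <- plsda_fit(d$X, d$y, n_components = 1, cv_folds = 4)
  ev <- plsda_evaluate(fit, d$X, d$y)
  flipped <- ifelse(d$y == "wild", "cultivated", "wild")
  ev_fl <- plsda_evaluate(fit, d$X, flipped)
  expect_equal(ev$acc_test + ev_fl$acc_test, 1)
})

test_that("a perfect test block of 33 + 19 scores 100% accuracy", {
  d <- two_clusters(n_per = 40, gap = 8, seed = 9)
  fit <- plsda_fit(d$X, d$y, n_components = 1, cv_folds = 5)
  set.seed(10)
  X_test <- rbind(matrix(rnorm(33 * 12), 33),
                  matrix(rnorm(19 * 12, mean = 8 / sqrt(12)), 19))
  y_test <- rep(c("cultivated", "wild"), c(33, 19))
  ev <- plsda_evaluate(fit, X_test, y_test)
  expect_equal(ev$acc_test, 1)
  expect_equal(ev$counts$TP, 19)
  expect_equal(ev$counts$TN, 33)
  expect_equal(ev$metrics$eff, 1)
})

test_that("full-rank PLS reproduces least-squares fitted indicators", {
  set.seed(13)
  n <- 10
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rep(c("wild", "cultivated"), 5)
  fit <- plsda_fit(X, y, n_components = 6, cv_folds = 5)
  Yc <- scale(mircos:::indicator_matrix(y, fit$classes), scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  ols <- lm.fit(Xc, Yc)
  expect_equal(Xc %*% fit$B, ols$fitted.values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PLS-DA class predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  d <- two_clusters(n_per = 18, gap = 4, seed = 17)
  colnames(d$X) <- paste0("v", 1:12)
  fit <- plsda_fit(d$X, d$y, n_components = 2, cv_folds = 5)
  set.seed(18)
  Xnew <- rbind(matrix(rnorm(10 * 12), 10),
                matrix(rnorm(10 * 12, mean = 4 / sqrt(12)), 10))
  colnames(Xnew) <- colnames(d$X)
  ours <- predict(fit, Xnew)$class
  mo <- mixOmics::plsda(d$X, factor(d$y), ncomp = 2, scale = FALSE)
  theirs <- as.character(predict(mo, Xnew)$class$max.dist[, 2])
  expect_equal(ours, theirs)
})

test_that("permutation test separates real signal from label noise", {
  d <- two_clusters(n_per = 15, gap = 5, seed = 23)
  res <- plsda_permutation_test(d$X, d$y, n_permutations = 30,
                                n_components = 2, cv_folds = 5, seed = 1)
  expect_lt(res$q2_intercept, 0)
  expect_false(res$overfit_flag)
  expect_equal(sum(res$table$permuted), 30)
  expect_equal(res$table$correlation[1], 1)

  set.seed(29)
  Xn <- matrix(rnorm(40 * 25), 40, 25)
  yn <- rep(c("wild", "cultivated"), 20)
  res_n <- plsda_permutation_test(Xn, yn, n_permutations = 30,
                                  n_components = 2, cv_folds = 5, seed = 2)
  expect_true(res_n$overfit_flag)

  expect_error(plsda_permutation_test(d$X, d$y, n_permutations = 5),
               class = "mircos_parameter_error")
})

test_that("the permutation test returns exactly the requested 200 rounds", {
  set.seed(31)
  X <- matrix(rnorm(24 * 10), 24, 10)
  y <- rep(c("wild", "cultivated"), 12)
  res <- plsda_permutation_test(X, y, n_permutations = 200,
                                n_components = 1, cv_folds = 4, seed = 3)
  expect_equal(sum(res$table$permuted), 200)
  expect_equal(nrow(res$table), 201)
})

test_that("SVM grid search finds a perfect cell on separable data with tie rules", {
  d <- two_clusters(n_per = 12, gap = 8, seed = 37)
  gs <- svm_grid_search(d$X, d$y, c_grid = 2^seq(-2, 8, 2),
                        g_grid = 2^seq(-8, -2, 2), cv_folds = 3, seed = 1)
  expect_equal(gs$best$cv_accuracy, 1)
  perfect <- gs$cv_table[gs$cv_table$cv_accuracy == 1, ]
  expect_equal(gs$best$c, min(perfect$c))
  expect_equal(gs$best$g, min(perfect$g[perfect$c == gs$best$c]))
  expect_true(gs$best$c %in% 2^seq(-2, 8, 2))
  preds <- svm_predict(gs, d$X)
  expect_gt(mean(preds == d$y), 0.9)

  one <- svm_grid_search(d$X, d$y, c_grid = 4, g_grid = 0.01,
                         cv_folds = 3, seed = 1)
  expect_equal(one$best$c, 4)
  expect_equal(one$best$g, 0.01)
  expect_error(svm_grid_search(d$X, d$y, c_grid = numeric(0), g_grid = 1),
               class = "mircos_parameter_error")
})
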