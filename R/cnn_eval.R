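#' Residual network architecture descriptor
#'
#' A compact residual CNN: an entry 3x3 convolution, then one stage per
#' entry of `widths`, each stage holding `blocks` identity-shortcut residual
#' blocks (two 3x3 convolutions each); stages after the first open with a
#' stride-2 transition convolution that halves the spatial resolution.
#' Global average pooling feeds a linear two-way head.
#'
#' @param widths channel width per stage.
#' @param blocks residual blocks per stage.
#' @return a list of class `resnet_spec`.
#' @export
resnet_spec <- function(widths = c(16, 32, 64), blocks = 2) {
  if (any(widths < 1) || blocks < 1)
    stop_mircos("mircos_parameter_error", "widths and blocks must be >= 1")
  structure(list(widths = as.integer(widths), blocks = as.integer(blocks)),
            class = "resnet_spec")
}

relu <- function(z) {
  z[z < 0] <- 0
  z
}

he_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

# Batch normalization over (H, W, batch) per channel; the residual
# branch's closing normalization starts at zero scale so every block is the
# identity at initialization, which keeps the early optimization landscape
# benign.
bn_forward_train <- function(z, g, b, eps = 1e-5) {
  d <- dim(z); C <- d[3]
  xhat <- z
  mu <- numeric(C); va <- numeric(C); inv <- numeric(C)
  for (c in seq_len(C)) {
    s <- z[, , c, , drop = FALSE]
    mu[c] <- mean(s)
    va[c] <- mean((s - mu[c])^2)
    inv[c] <- 1 / sqrt(va[c] + eps)
    xhat[, , c, ] <- (s - mu[c]) * inv[c]
  }
  y <- xhat
  for (c in seq_len(C)) y[, , c, ] <- g[c] * xhat[, , c, ] + b[c]
  list(y = y, xhat = xhat, inv = inv, mu = mu, va = va)
}

bn_forward_eval <- function(z, g, b, mu, va, eps = 1e-5) {
  for (c in seq_along(g))
    z[, , c, ] <- g[c] * (z[, , c, ] - mu[c]) / sqrt(va[c] + eps) + b[c]
  z
}

bn_backward <- function(dy, xhat, inv, g) {
  d <- dim(dy); C <- d[3]
  m <- d[1] * d[2] * d[4]
  dg <- numeric(C); db <- numeric(C)
  dx <- dy
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xh <- xhat[, , c, , drop = FALSE]
    dg[c] <- sum(dyc * xh)
    db[c] <- sum(dyc)
    dxhat <- g[c] * dyc
    dx[, , c, ] <- inv[c] / m * (m * dxhat - sum(dxhat) - xh * sum(dxhat * xh))
  }
  list(dx = dx, dg = dg, db = db)
}

# Conv units in execution order; each is conv + batch norm.
unit_names <- function(arch) {
  out <- "conv0"
  for (s in seq_along(arch$widths)) {
    if (s > 1) out <- c(out, sprintf("t%d", s))
    for (bl in seq_len(arch$blocks))
      out <- c(out, sprintf("s%db%da", s, bl), sprintf("s%db%db", s, bl))
  }
  out
}

unit_width <- function(arch, nm) {
  if (nm == "conv0") return(arch$widths[1])
  arch$widths[as.integer(substr(nm, 2, 2))]
}

init_resnet <- function(arch, in_channels = 3L, n_classes = 2L, seed = 1L) {
  set.seed(seed)
  p <- list()
  w <- arch$widths
  cin <- in_channels
  for (nm in unit_names(arch)) {
    cout <- unit_width(arch, nm)
    p[[paste0(nm, ".w")]] <- he_conv(3, cin, cout)
    p[[paste0(nm, ".b")]] <- rep(0, cout)
    # zero gamma on the residual branch's closing normalization
    gamma0 <- if (grepl("b$", nm)) 0 else 1
    p[[paste0(nm, ".g")]] <- rep(gamma0, cout)
    p[[paste0(nm, ".be")]] <- rep(0, cout)
    cin <- cout
  }
  p[["fc.w"]] <- matrix(rnorm(n_classes * w[length(w)], 0,
                              sqrt(2 / w[length(w)])),
                        n_classes, w[length(w)])
  p[["fc.b"]] <- rep(0, n_classes)
  p
}

init_bn_stats <- function(arch) {
  st <- list()
  for (nm in unit_names(arch)) {
    cout <- unit_width(arch, nm)
    st[[nm]] <- list(mean = rep(0, cout), var = rep(1, cout))
  }
  st
}

forward_resnet <- function(params, arch, x, bn_stats, train = FALSE,
                           keep_cache = FALSE, bn_momentum = 0.1) {
  cache <- list()
  conv_bn <- function(nm, xin, stride) {
    z <- conv2d_forward(xin, params[[paste0(nm, ".w")]],
                        params[[paste0(nm, ".b")]], stride, 1L)
    if (train) {
      bn <- bn_forward_train(z, params[[paste0(nm, ".g")]],
                             params[[paste0(nm, ".be")]])
      bn_stats[[nm]]$mean <<- (1 - bn_momentum) * bn_stats[[nm]]$mean +
        bn_momentum * bn$mu
      bn_stats[[nm]]$var <<- (1 - bn_momentum) * bn_stats[[nm]]$var +
        bn_momentum * bn$va
      if (keep_cache)
        cache[[nm]] <<- list(xin = xin, xhat = bn$xhat, inv = bn$inv)
      bn$y
    } else {
      bn_forward_eval(z, params[[paste0(nm, ".g")]],
                      params[[paste0(nm, ".be")]],
                      bn_stats[[nm]]$mean, bn_stats[[nm]]$var)
    }
  }

  h <- relu(y0 <- conv_bn("conv0", x, 1L))
  if (keep_cache) cache$y0 <- y0
  for (s in seq_along(arch$widths)) {
    if (s > 1) {
      nm <- sprintf("t%d", s)
      yt <- conv_bn(nm, h, 2L)
      if (keep_cache) cache[[paste0(nm, ".y")]] <- yt
      h <- relu(yt)
    }
    for (bl in seq_len(arch$blocks)) {
      key <- sprintf("s%db%d", s, bl)
      ya <- conv_bn(paste0(key, "a"), h, 1L)
      ha <- relu(ya)
      yb <- conv_bn(paste0(key, "b"), ha, 1L)
      zs <- h + yb
      if (keep_cache) {
        cache[[paste0(key, ".ya")]] <- ya
        cache[[paste0(key, ".zs")]] <- zs
      }
      h <- relu(zs)
    }
  }
  d <- dim(h)
  v <- matrix(colMeans(matrix(h, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  if (keep_cache) { cache$hdim <- d; cache$v <- v }
  logits <- params[["fc.w"]] %*% v + params[["fc.b"]]
  list(logits = logits, cache = cache, bn_stats = bn_stats)
}

backward_resnet <- function(params, arch, cache, dlogits) {
  g <- list()
  conv_bn_bw <- function(nm, dy, stride) {
    cc <- cache[[nm]]
    bn <- bn_backward(dy, cc$xhat, cc$inv, params[[paste0(nm, ".g")]])
    g[[paste0(nm, ".g")]] <<- bn$dg
    g[[paste0(nm, ".be")]] <<- bn$db
    cv <- conv2d_backward(cc$xin, params[[paste0(nm, ".w")]], bn$dx,
                          stride, 1L)
    g[[paste0(nm, ".w")]] <<- cv$dw
    g[[paste0(nm, ".b")]] <<- cv$db
    cv$dx
  }

  g[["fc.w"]] <- dlogits %*% t(cache$v)
  g[["fc.b"]] <- rowSums(dlogits)
  d <- cache$hdim
  dv <- t(params[["fc.w"]]) %*% dlogits
  dh <- array(rep(as.vector(dv) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  for (s in rev(seq_along(arch$widths))) {
    for (bl in rev(seq_len(arch$blocks))) {
      key <- sprintf("s%db%d", s, bl)
      dzs <- dh * (cache[[paste0(key, ".zs")]] > 0)
      dha <- conv_bn_bw(paste0(key, "b"), dzs, 1L)
      dya <- dha * (cache[[paste0(key, ".ya")]] > 0)
      dh <- dzs + conv_bn_bw(paste0(key, "a"), dya, 1L)
    }
    if (s > 1) {
      nm <- sprintf("t%d", s)
      dyt <- dh * (cache[[paste0(nm, ".y")]] > 0)
      dh <- conv_bn_bw(nm, dyt, 2L)
    }
  }
  dy0 <- dh * (cache$y0 > 0)
  conv_bn_bw("conv0", dy0, 1L)
  g
}

softmax_ce <- function(logits, yidx) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(yidx, seq_len(n))], 1e-12)))
  dlogits <- p
  dlogits[cbind(yidx, seq_len(n))] <- dlogits[cbind(yidx, seq_len(n))] - 1
  list(loss = loss, dlogits = dlogits / n, prob = p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

load_role_images <- function(dataset, category, role) {
  man <- dataset$manifest
  sub <- man[man$category == category & man$role == role, , drop = FALSE]
  if (nrow(sub) == 0)
    stop_mircos("mircos_dataset_error", "no images for category '", category,
                "', role '", role, "'")
  sub <- sub[order(sub$sample_id), , drop = FALSE]
  imgs <- lapply(sub$path, read_image_array)
  d <- dim(imgs[[1]])
  x <- array(unlist(imgs, use.names = FALSE), dim = c(d[1], d[2], 3, nrow(sub)))
  list(x = x, labels = sub$class, ids = sub$sample_id)
}

normalize_images <- function(x, norm) {
  for (c in 1:3) x[, , c, ] <- (x[, , c, ] - norm$mean[c]) / norm$sd[c]
  x
}

#' Train the residual CNN on a correlation-map image category
#'
#' Mini-batch Adam training of the [resnet_spec()] network on the `train`
#' role, with per-epoch loss and train/test accuracies recorded.
#' Deterministic for a fixed seed (weight initialization and batch shuffling
#' are the only random elements). Per-channel normalization constants are
#' computed from the training role only. With `early_stop = TRUE` training
#' ends once test-role accuracy has held at 100% for `patience` consecutive
#' epochs (training histories are then no longer length-comparable across
#' runs, so it is off by default).
#'
#' @param dataset an [build_image_dataset()] result.
#' @param category image category to train on (default `"synchronous"`).
#' @param epochs maximum training epochs (default 46).
#' @param seed RNG seed for initialization and shuffling.
#' @param arch a [resnet_spec()].
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param early_stop stop after sustained perfect test accuracy.
#' @param patience consecutive perfect epochs required when `early_stop`.
#' @param positive positive class (default `"wild"`).
#' @param verbose print per-epoch progress.
#' @return a `cnn_model` list: `params`, `arch`, `norm`, `classes`,
#'   `category`, `seed`, and `history` (data.frame
#'   `epoch,loss,acc_train,acc_test`).
#' @export
train_classifier <- function(dataset, category = "synchronous", epochs = 46,
                             seed = 1, arch = resnet_spec(), lr = 3e-3,
                             batch_size = 16, early_stop = FALSE, patience = 5,
                             positive = "wild", verbose = FALSE) {
  tr <- load_role_images(dataset, category, "train")
  te <- load_role_images(dataset, category, "test")
  classes <- sort(unique(c(tr$labels, te$labels)))
  if (length(classes) != 2)
    stop_mircos("mircos_dataset_error", "exactly two classes required")

  norm <- list(mean = vapply(1:3, function(c) mean(tr$x[, , c, ]), 0),
               sd = vapply(1:3, function(c) max(sd(tr$x[, , c, ]), 1e-8), 0))
  xtr <- normalize_images(tr$x, norm)
  xte <- normalize_images(te$x, norm)
  ytr <- match(tr$labels, classes)
  yte <- match(te$labels, classes)
  n_tr <- length(ytr)

  set.seed(seed)
  params <- init_resnet(arch, in_channels = 3L, n_classes = 2L,
                        seed = derive_seed(seed, "init"))
  bn_stats <- init_bn_stats(arch)
  state <- adam_init(params)

  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     acc_train = numeric(0), acc_test = numeric(0))
  streak <- 0L
  set.seed(derive_seed(seed, "shuffle"))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_tr)
    losses <- c()
    correct <- 0L
    for (start in seq(1, n_tr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n_tr)]
      xb <- xtr[, , , idx, drop = FALSE]
      fw <- forward_resnet(params, arch, xb, bn_stats, train = TRUE,
                           keep_cache = TRUE)
      bn_stats <- fw$bn_stats
      sc <- softmax_ce(fw$logits, ytr[idx])
      if (!is.finite(sc$loss))
        stop_mircos("mircos_divergence_error", "non-finite loss at epoch ", ep)
      losses <- c(losses, sc$loss)
      correct <- correct + sum(apply(sc$prob, 2, which.max) == ytr[idx])
      grads <- backward_resnet(params, arch, fw$cache, sc$dlogits)
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
    }
    acc_tr <- correct / n_tr
    pte <- forward_resnet(params, arch, xte, bn_stats)$logits
    acc_te <- mean(classes[apply(pte, 2, which.max)] == te$labels)
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   acc_train = acc_tr, acc_test = acc_te))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.3f  test %.3f",
                      ep, mean(losses), acc_tr, acc_te))
    streak <- if (acc_te == 1) streak + 1L else 0L
    if (early_stop && streak >= patience) break
  }
  structure(list(params = params, arch = arch, bn_stats = bn_stats,
                 norm = norm, classes = classes,
                 category = category, seed = seed, positive = positive,
                 history = hist),
            class = "cnn_model")
}

#' Evaluate a trained CNN on a dataset role
#'
#' Argmax predictions on the requested role, scored as confusion counts with
#' the model's positive class, the Eq-style metric layer
#' ([confusion_metrics()]) and the mean cross-entropy loss. The external
#' validation role is required to be disjoint (by sample id) from the
#' training and test roles.
#'
#' @param model a `cnn_model` from [train_classifier()].
#' @param dataset the `image_dataset` to score.
#' @param role one of `"train"`, `"test"`, `"ev"`.
#' @return list with `counts`, `metrics`, `loss`, `predictions`, `ids`.
#' @export
evaluate_classifier <- function(model, dataset, role = "ev") {
  ld <- load_role_images(dataset, model$category, role)
  man <- dataset$manifest
  if (role == "ev") {
    fitted_ids <- man$sample_id[man$role %in% c("train", "test")]
    overlap <- intersect(ld$ids, fitted_ids)
    if (length(overlap))
      stop_mircos("mircos_leakage_error",
                  "external-validation ids overlap train/test: ",
                  paste(head(overlap, 3), collapse = ", "))
  }
  x <- normalize_images(ld$x, model$norm)
  y <- match(ld$labels, model$classes)
  n <- length(y)
  preds <- character(n)
  losses <- numeric(0)
  for (start in seq(1, n, by = 32)) {
    idx <- start:min(start + 31, n)
    fw <- forward_resnet(model$params, model$arch,
                         x[, , , idx, drop = FALSE], model$bn_stats)
    sc <- softmax_ce(fw$logits, y[idx])
    losses <- c(losses, sc$loss * length(idx))
    preds[idx] <- model$classes[apply(sc$prob, 2, which.max)]
  }
  counts <- confusion_counts(ld$labels, preds, positive = model$positive)
  list(counts = counts, metrics = confusion_metrics(counts),
       loss = sum(losses) / n, predictions = preds, ids = ld$ids)
}
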