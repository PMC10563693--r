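#' Principal component analysis of a spectral matrix
#'
#' Mean-centered SVD; explained-variance ratios are singular values squared
#' over the total variance.
#'
#' @param X numeric matrix, records in rows.
#' @param k number of components (<= min(n - 1, p)).
#' @return list with `scores` (n x k), `loadings` (p x k),
#'   `explained_variance_ratio` (length k).
#' @export
pca_fit <- function(X, k = 2) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop_mircos("mircos_parameter_error", "PCA needs n >= 2")
  if (k > min(n - 1, p))
    stop_mircos("mircos_parameter_error", "k exceeds min(n - 1, p)")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance_ratio = ev[seq_len(k)] / sum(ev))
}

# Indicator coding: one centered column per class.
indicator_matrix <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

# NIPALS PLS2 on centered X and Y. Returns weights/loadings/scores and the
# regression matrix B with Yhat = Xc %*% B.
nipals_pls <- function(Xc, Yc, ncomp, tol = 1e-12, max_iter = 500) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  X1 <- Xc; Y1 <- Yc
  for (a in seq_len(ncomp)) {
    u <- Y1[, which.max(colSums(Y1^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X1, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300)
        stop_mircos("mircos_rank_error",
                    "X residual exhausted: reduce n_components")
      w <- w / nw
      tt <- X1 %*% w
      qv <- crossprod(Y1, tt) / sum(tt^2)
      u <- Y1 %*% qv / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pv <- crossprod(X1, tt) / sum(tt^2)
    X1 <- X1 - tt %*% t(pv)
    Y1 <- Y1 - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; TT[, a] <- tt
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(W = W, P = P, Q = Q, T = TT, B = B)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis by NIPALS on the centered
#' spectral matrix and centered class-indicator columns, with the argmax
#' decision rule. Cumulative R2Y and training RMSEE come from the fit;
#' Q2 and RMSECV from deterministic stratified k-fold cross-validation with
#' a full per-fold refit (Q2 = 1 - PRESS/TSS on the centered indicator
#' scale).
#'
#' @param X numeric matrix (records x variables).
#' @param y class labels (two classes).
#' @param n_components latent variables to extract, or `"auto"` to grow the
#'   model while each added component improves Q2.
#' @param cv_folds folds for Q2/RMSECV (default 7).
#' @param max_components cap used when `n_components = "auto"`.
#' @return a `plsda_model` with the fit, `metrics` (R2Y, Q2, RMSEE, RMSECV,
#'   acc_train) and the coding needed for prediction.
#' @export
plsda_fit <- function(X, y, n_components = 2, cv_folds = 7,
                      max_components = 10) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2)
    stop_mircos("mircos_class_error", "exactly two classes required, got ",
                length(classes))
  n <- nrow(X)

  if (identical(n_components, "auto")) {
    best_a <- 1
    q2_prev <- -Inf
    for (a in seq_len(min(max_components, n - 2, ncol(X)))) {
      q2a <- plsda_cv(X, y, classes, a, cv_folds)$Q2
      if (q2a > q2_prev) { best_a <- a; q2_prev <- q2a } else break
    }
    n_components <- best_a
  }
  if (n_components < 1 || n_components > min(n - 1, ncol(X)))
    stop_mircos("mircos_parameter_error", "n_components out of range")

  x_mean <- colMeans(X)
  Y <- indicator_matrix(y, classes)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  fit <- nipals_pls(Xc, Yc, n_components)

  Yhat_c <- Xc %*% fit$B
  rss <- sum((Yc - Yhat_c)^2)
  tss <- sum(Yc^2)
  cv <- plsda_cv(X, y, classes, n_components, cv_folds)
  Yhat <- sweep(Yhat_c, 2, y_mean, "+")
  pred <- classes[apply(Yhat, 1, which.max)]

  structure(list(
    B = fit$B, W = fit$W, P = fit$P, Q = fit$Q, T = fit$T,
    x_mean = x_mean, y_mean = y_mean, classes = classes,
    n_components = n_components, cv_folds = cv_folds,
    residuals = Y - Yhat,
    metrics = list(R2Y = 1 - rss / tss, Q2 = cv$Q2,
                   RMSEE = sqrt(rss / length(Yc)), RMSECV = cv$RMSECV,
                   acc_train = mean(pred == y))),
    class = "plsda_model")
}

plsda_cv <- function(X, y, classes, ncomp, k) {
  Y <- indicator_matrix(y, classes)
  Yc_all <- sweep(Y, 2, colMeans(Y))
  fold <- stratified_folds(y, k)
  press <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    x_mean <- colMeans(X[tr, , drop = FALSE])
    y_mean <- colMeans(Y[tr, , drop = FALSE])
    fit <- nipals_pls(sweep(X[tr, , drop = FALSE], 2, x_mean),
                      sweep(Y[tr, , drop = FALSE], 2, y_mean),
                      min(ncomp, sum(tr) - 1))
    Yhat <- sweep(sweep(X[!tr, , drop = FALSE], 2, x_mean) %*% fit$B,
                  2, y_mean, "+")
    press <- press + sum((Y[!tr, , drop = FALSE] - Yhat)^2)
  }
  list(Q2 = 1 - press / sum(Yc_all^2), RMSECV = sqrt(press / length(Y)))
}

#' Predict classes and indicator values from a PLS-DA model
#' @param object a `plsda_model`; `newdata` spectral matrix on the training
#'   variable grid.
#' @param newdata matrix of new records.
#' @param ... unused.
#' @return list with `class` (argmax rule) and `Yhat` (indicator scale).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop_mircos("mircos_dim_error", "variable grid mismatch")
  Yhat <- sweep(sweep(newdata, 2, object$x_mean) %*% object$B,
                2, object$y_mean, "+")
  list(class = object$classes[apply(Yhat, 1, which.max)], Yhat = Yhat)
}

#' Evaluate a PLS-DA model on a test set
#'
#' @param model a `plsda_model`.
#' @param X_test,y_test held-out records and labels.
#' @param positive positive class for the confusion counts.
#' @return list with `RMSEP`, `acc_test`, `counts`, `metrics`.
#' @export
plsda_evaluate <- function(model, X_test, y_test, positive = "wild") {
  pr <- predict(model, X_test)
  Y <- indicator_matrix(as.character(y_test), model$classes)
  counts <- confusion_counts(as.character(y_test), pr$class, positive)
  list(RMSEP = sqrt(mean((Y - pr$Yhat)^2)),
       acc_test = mean(pr$class == y_test),
       counts = counts, metrics = confusion_metrics(counts))
}

#' PLS-DA permutation test
#'
#' Refits the model `n_permutations` times on label permutations, recording
#' each permutation's R2Y and Q2 against the absolute Pearson correlation
#' between the permuted and original indicator vectors. Straight lines
#' through all points (the unpermuted model included at correlation 1) give
#' the R2/Q2 intercepts; a fitted model is flagged as overfitted when the Q2
#' intercept is nonnegative or any permutation matches/exceeds the original
#' R2Y or Q2.
#'
#' @param X,y data and labels.
#' @param n_permutations number of permutations (default 200, >= 10).
#' @param n_components,cv_folds fixed model configuration.
#' @param seed RNG seed for the permutations.
#' @return a `permutation_result` with `table` (correlation, R2Y, Q2 per
#'   permutation plus the original), `r2_intercept`, `q2_intercept`,
#'   `overfit_flag`.
#' @export
plsda_permutation_test <- function(X, y, n_permutations = 200,
                                   n_components = 2, cv_folds = 7, seed = 1) {
  if (n_permutations < 10)
    stop_mircos("mircos_parameter_error", "need at least 10 permutations")
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  y1 <- as.numeric(y == classes[1])

  fit0 <- plsda_fit(X, y, n_components, cv_folds)
  tab <- data.frame(correlation = 1, R2Y = fit0$metrics$R2Y,
                    Q2 = fit0$metrics$Q2, permuted = FALSE)
  set.seed(seed)
  for (i in seq_len(n_permutations)) {
    yp <- sample(y)
    fit <- plsda_fit(X, yp, n_components, cv_folds)
    tab <- rbind(tab, data.frame(
      correlation = abs(cor(as.numeric(yp == classes[1]), y1)),
      R2Y = fit$metrics$R2Y, Q2 = fit$metrics$Q2, permuted = TRUE))
  }
  r2_line <- lm(R2Y ~ correlation, data = tab)
  q2_line <- lm(Q2 ~ correlation, data = tab)
  perm <- tab[tab$permuted, ]
  structure(list(
    table = tab,
    r2_intercept = unname(coef(r2_line)[1]),
    q2_intercept = unname(coef(q2_line)[1]),
    overfit_flag = unname(coef(q2_line)[1]) >= 0 ||
      any(perm$R2Y >= fit0$metrics$R2Y) || any(perm$Q2 >= fit0$metrics$Q2)),
    class = "permutation_result")
}

#' RBF-SVM grid search with cross-validated accuracy
#'
#' Trains a radial-kernel SVM at every (cost, gamma) pair of a base-2 grid,
#' scores each by stratified k-fold CV accuracy on column-standardized
#' features, and refits the best pair (ties broken toward smaller cost, then
#' smaller gamma) on the full training set.
#'
#' @param X_train,y_train training records and labels.
#' @param c_grid,g_grid candidate cost and kernel-width values.
#' @param cv_folds CV folds (default 5).
#' @param seed seed for fold shuffling.
#' @return list with `model` (e1071::svm fit on standardized features),
#'   `best` (`c`, `g`, `cv_accuracy`), `cv_table`, and the standardization
#'   (`center`, `scale`) to apply to new records.
#' @export
svm_grid_search <- function(X_train, y_train, c_grid = 2^(-10:20),
                            g_grid = 2^(-20:4), cv_folds = 5, seed = 1) {
  if (!length(c_grid) || !length(g_grid))
    stop_mircos("mircos_parameter_error", "empty grid")
  X_train <- as.matrix(X_train)
  y_train <- factor(as.character(y_train))
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X_train, 2, ctr), 2, scl, "/")

  set.seed(seed)
  fold <- integer(length(y_train))
  for (cl in levels(y_train)) {
    idx <- which(y_train == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  if (min(table(fold, y_train)) == 0)
    stop_mircos("mircos_resampling_error", "a CV fold lost a class")

  grid <- expand.grid(c = sort(c_grid), g = sort(g_grid))
  grid <- grid[order(grid$c, grid$g), ]
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      m <- e1071::svm(Xs[tr, , drop = FALSE], y_train[tr],
                      kernel = "radial", cost = grid$c[i], gamma = grid$g[i],
                      scale = FALSE)
      hits <- hits + sum(predict(m, Xs[!tr, , drop = FALSE]) == y_train[!tr])
    }
    acc[i] <- hits / length(y_train)
  }
  best_i <- which.max(acc)   # first maximum = smallest c, then smallest g
  best <- list(c = grid$c[best_i], g = grid$g[best_i],
               cv_accuracy = acc[best_i])
  model <- e1071::svm(Xs, y_train, kernel = "radial", cost = best$c,
                      gamma = best$g, scale = FALSE)
  list(model = model, best = best,
       cv_table = cbind(grid, cv_accuracy = acc),
       center = ctr, scale = scl)
}

#' Predict with a grid-searched SVM on new records
#' @param fit result of [svm_grid_search()]; `newdata` records on the
#'   training variable grid.
#' @param newdata matrix of new records.
#' @export
svm_predict <- function(fit, newdata) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, fit$center), 2, fit$scale, "/")
  as.character(predict(fit$model, Xs))
}
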