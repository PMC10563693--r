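#' Kennard-Stone maxmin selection
#'
#' Classical deterministic calibration-set selection: the first two picks are
#' the pair at maximum Euclidean distance; every further pick maximizes its
#' minimum distance to the already-selected records. Ties are broken by the
#' lowest row index, so the result is fully deterministic; callers that want
#' order-independence should pass rows in a canonical order.
#'
#' @param X numeric matrix, records in rows.
#' @param n_select number of records to select (2..nrow(X)).
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone_select <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2) stop_mircos("mircos_parameter_error", "n_select must be >= 2")
  if (n_select > n) stop_mircos("mircos_parameter_error", "n_select exceeds record count")
  d <- as.matrix(stats::dist(X))
  # starting pair: maximum distance, lowest (i, j) on ties
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0L) best <- matrix(c(1L, 2L), 1)  # all points coincide
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1, ])
  if (n_select > 2) {
    mind <- pmin(d[, sel[1]], d[, sel[2]])
    for (k in 3:n_select) {
      mind[sel] <- -Inf
      pick <- which.max(mind)          # which.max takes the first maximum
      sel <- c(sel, pick)
      mind <- pmin(mind, d[, pick])
    }
  }
  unname(sel)
}

#' Stratified 70/30 Kennard-Stone split
#'
#' Kennard-Stone selection run independently within each class on the
#' (replicate-averaged) spectra; the training share of each class is
#' `floor(fraction * class size)` and the remainder forms the test set. With
#' the study's class sizes, 109 cultivated and 63 wild at fraction 0.7, this
#' reproduces the printed 76/44 training and 33/19 test partition.
#'
#' @param x a `SpectraSet`.
#' @param fraction training fraction in (0, 1).
#' @param space representation in which distances are computed: `"raw"` or a
#'   preprocessing chain name understood by [apply_chain()].
#' @return a `split_result` list: `train_ids`, `test_ids`, `per_class_counts`
#'   (matrix with `n_train`/`n_test` rows), `method`.
#' @export
stratified_split <- function(x, fraction = 0.7, space = "raw") {
  stopifnot(inherits(x, "SpectraSet"))
  if (fraction <= 0 || fraction >= 1)
    stop_mircos("mircos_parameter_error", "fraction must be in (0, 1)")
  avg <- average_replicates(x)
  rep_spectra <- if (identical(space, "raw")) avg else apply_chain(avg, space)

  # canonical ordering by sample_id so selection ignores record shuffling
  ord <- order(avg$sample_ids)
  ids <- avg$sample_ids[ord]
  labs <- avg$labels[ord]
  M <- rep_spectra$absorbance[ord, , drop = FALSE]

  train_ids <- character(0)
  counts <- matrix(0L, nrow = 2, ncol = 2,
                   dimnames = list(c("n_train", "n_test"), avg$classes))
  for (cl in avg$classes) {
    in_cl <- which(labs == cl)
    if (length(in_cl) < 3)
      stop_mircos("mircos_stratification_error", "class '", cl,
                  "' has fewer than 3 samples")
    n_train <- floor(fraction * length(in_cl))
    if (n_train < 2 || n_train >= length(in_cl))
      stop_mircos("mircos_parameter_error",
                  "fraction leaves class '", cl, "' without train or test samples")
    sel <- kennard_stone_select(M[in_cl, , drop = FALSE], n_train)
    train_ids <- c(train_ids, ids[in_cl[sel]])
    counts["n_train", cl] <- n_train
    counts["n_test", cl] <- length(in_cl) - n_train
  }
  test_ids <- setdiff(ids, train_ids)
  structure(list(train_ids = sort(train_ids), test_ids = sort(test_ids),
                 per_class_counts = counts, method = "kennard_stone"),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result (%s): %d train / %d test\n", x$method,
              length(x$train_ids), length(x$test_ids)))
  print(x$per_class_counts)
  invisible(x)
}

#' Write / read a split manifest (`sample_id,role` CSV)
#' @param split a `split_result`.
#' @param path CSV path.
#' @export
write_split_csv <- function(split, path) {
  df <- rbind(data.frame(sample_id = split$train_ids, role = "train"),
              data.frame(sample_id = split$test_ids, role = "test"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
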