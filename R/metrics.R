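#' Confusion counts
#'
#' Tally a two-class confusion matrix with a declared positive class (the
#' adulteration target, `wild`, throughout this workflow).
#'
#' @param truth,predicted class vectors of equal length.
#' @param positive the positive class name.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "wild") {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, positive = positive),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and effectivity from confusion counts
#'
#' `acc = (TP + TN) / total`, `sen = TP / (TP + FN)`,
#' `spe = TN / (TN + FP)`, `eff = sen * spe`. All returned as fractions in
#' `[0, 1]`; note `eff` is the *product* of sensitivity and specificity, so
#' it equals them only when both are 0 or 1.
#'
#' @param counts a [confusion_counts()] object, or `TP` given all four
#'   counts separately.
#' @param TN,FP,FN individual counts when `counts` is numeric `TP`.
#' @return a `classifier_metrics` list with `acc`, `sen`, `spe`, `eff`.
#' @export
confusion_metrics <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (is.numeric(counts) && !is.null(TN)) {
    counts <- structure(list(TP = counts, TN = TN, FP = FP, FN = FN),
                        class = "confusion_counts")
  }
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0)
    stop_mircos("mircos_metric_error", "accuracy undefined: no samples")
  if (tp + fn == 0)
    stop_mircos("mircos_metric_error", "sensitivity undefined: no positives")
  if (tn + fp == 0)
    stop_mircos("mircos_metric_error", "specificity undefined: no negatives")
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  structure(list(acc = (tp + tn) / total, sen = sen, spe = spe,
                 eff = sen * spe),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("acc %.4f  sen %.4f  spe %.4f  eff %.4f\n",
              x$acc, x$sen, x$spe, x$eff))
  invisible(x)
}
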