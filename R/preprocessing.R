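#' Standard normal variate transformation
#'
#' Centers and scales every record to mean 0 and unit standard deviation
#' (sample, n-1 denominator) across wavenumbers, removing per-record
#' multiplicative scatter and additive offset.
#'
#' @param x a `SpectraSet`.
#' @return the transformed `SpectraSet`.
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "SpectraSet"))
  m <- rowMeans(x$absorbance)
  s <- apply(x$absorbance, 1, sd)
  if (any(s == 0))
    stop_mircos("mircos_degenerate_error", "constant record (sd = 0): ",
                rownames(x$absorbance)[which(s == 0)[1]])
  out <- x
  out$absorbance <- (x$absorbance - m) / s
  rownames(out$absorbance) <- rownames(x$absorbance)
  out
}

#' Mean spectrum for use as an MSC reference
#' @param x a `SpectraSet`.
#' @return numeric vector on the set's grid.
#' @export
msc_reference <- function(x) colMeans(x$absorbance)

#' Multiplicative scatter correction
#'
#' Each record is regressed on the reference spectrum by ordinary least
#' squares, `x = a + b * ref`, and returned as `(x - a) / b`, exactly
#' inverting an affine distortion of the reference. To avoid train/test
#' leakage, fit the reference on the training records ([msc_reference()])
#' and pass the same vector when transforming held-out records.
#'
#' @param x a `SpectraSet`.
#' @param reference reference spectrum on the same grid; defaults to the mean
#'   spectrum of `x`.
#' @return the corrected `SpectraSet`.
#' @export
msc <- function(x, reference = NULL) {
  stopifnot(inherits(x, "SpectraSet"))
  ref <- reference %||% msc_reference(x)
  if (length(ref) != length(x$wavenumbers))
    stop_mircos("mircos_dim_error", "MSC reference not on the set's grid")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  if (denom == 0)
    stop_mircos("mircos_degenerate_error", "MSC reference is constant")
  out <- x
  for (i in seq_len(n_records(x))) {
    xi <- x$absorbance[i, ]
    b <- sum((xi - mean(xi)) * rc) / denom
    if (b == 0)
      stop_mircos("mircos_degenerate_error", "zero MSC slope for record ",
                  rownames(x$absorbance)[i])
    a <- mean(xi) - b * mean(ref)
    out$absorbance[i, ] <- (xi - a) / b
  }
  out
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local polynomial filtering per record. Derivatives are rescaled by the
#' (signed) grid step so they are physical derivatives with respect to
#' wavenumber (per cm^-1, to the power of the derivative order), independent
#' of grid direction. Edge points come from the one-sided polynomial fits of
#' the filter's startup/shutdown rows, so polynomial signals of degree <=
#' `polyorder` are reproduced exactly everywhere, edges included.
#'
#' @param x a `SpectraSet`.
#' @param window odd filter length in points (> `polyorder`).
#' @param polyorder fitted polynomial degree.
#' @param deriv_order derivative order (0 = smoothing), <= `polyorder`.
#' @return the filtered `SpectraSet`.
#' @export
savitzky_golay <- function(x, window = 15, polyorder = 3, deriv_order = 0) {
  stopifnot(inherits(x, "SpectraSet"))
  if (window %% 2 == 0 || window <= polyorder)
    stop_mircos("mircos_parameter_error",
                "window must be odd and greater than polyorder")
  if (deriv_order > polyorder || deriv_order < 0)
    stop_mircos("mircos_parameter_error", "deriv_order must be in 0..polyorder")
  if (length(x$wavenumbers) < window)
    stop_mircos("mircos_parameter_error", "window longer than the grid")
  step <- x$wavenumbers[2] - x$wavenumbers[1]
  out <- x
  scale <- step^deriv_order
  for (i in seq_len(n_records(x))) {
    out$absorbance[i, ] <- signal::sgolayfilt(
      x$absorbance[i, ], p = polyorder, n = window, m = deriv_order) / scale
  }
  out
}

# The preprocessing chains of the workflow, named as practitioners write
# them. 1D/2D are Savitzky-Golay derivatives (window 15, polyorder 3); SG
# alone is smoothing.
chain_names <- function() {
  c("RAW", "1D", "2D", "SNV", "MSC", "SG", "SNV+2D", "MSC+2D", "SG+2D")
}

parse_chain <- function(chain) {
  steps <- trimws(strsplit(chain, "+", fixed = TRUE)[[1]])
  known <- c("RAW", "1D", "2D", "SNV", "MSC", "SG")
  bad <- setdiff(steps, known)
  if (length(bad) || !length(steps))
    stop_mircos("mircos_parameter_error", "unknown preprocessing step: ",
                paste(bad, collapse = ", "))
  steps
}

#' Apply a named preprocessing chain
#'
#' Steps are applied left to right. `1D`/`2D` are first/second Savitzky-Golay
#' derivatives and `SG` is Savitzky-Golay smoothing, all with window 15 and
#' polynomial order 3; `RAW` is the identity. For chains containing `MSC`,
#' pass the frozen training-set reference via `msc_ref` when transforming
#' held-out records (fit it once with [msc_reference()] on the training set).
#'
#' @param x a `SpectraSet`.
#' @param chain chain name: RAW, 1D, 2D, SNV, MSC, SG, SNV+2D, MSC+2D or SG+2D.
#' @param msc_ref optional frozen MSC reference spectrum.
#' @param window,polyorder Savitzky-Golay filter settings.
#' @return the transformed `SpectraSet`.
#' @export
apply_chain <- function(x, chain, msc_ref = NULL, window = 15, polyorder = 3) {
  for (step in parse_chain(chain)) {
    x <- switch(step,
      RAW = x,
      SNV = snv(x),
      MSC = msc(x, reference = msc_ref),
      SG  = savitzky_golay(x, window, polyorder, 0),
      "1D" = savitzky_golay(x, window, polyorder, 1),
      "2D" = savitzky_golay(x, window, polyorder, 2))
  }
  x
}
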