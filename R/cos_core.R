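#' Hilbert-Noda transformation matrix
#'
#' The antisymmetric weight matrix of generalized two-dimensional correlation
#' spectroscopy: `N[j, k] = 0` on the diagonal and `1 / (pi * (k - j))` off
#' it, so `N + t(N) = 0`.
#'
#' @param m perturbation-series length (>= 1).
#' @return an `m x m` numeric matrix.
#' @export
hilbert_noda_matrix <- function(m) {
  if (m < 1) stop_mircos("mircos_parameter_error", "m must be >= 1")
  j <- seq_len(m)
  diffs <- outer(j, j, function(a, b) b - a)
  N <- ifelse(diffs == 0, 0, 1 / (pi * diffs))
  N
}

#' Dynamic spectra of a perturbation series
#'
#' Subtracts a reference spectrum from every record of the series. The
#' default reference is the series mean, the standard convention that makes
#' the synchronous map a covariance (its diagonal the per-wavenumber
#' variance); a supplied reference vector is used verbatim (raw-equation
#' mode: pass a zero vector).
#'
#' @param series a `SpectraSet` whose records form the perturbation series.
#' @param reference `"mean"` (default) or a numeric spectrum on the grid.
#' @return list of class `dynamic_spectra`: `D` (m x n matrix), `reference`,
#'   `m`, `wavenumbers`.
#' @export
dynamic_spectra <- function(series, reference = "mean") {
  stopifnot(inherits(series, "SpectraSet"))
  m <- n_records(series)
  if (m < 2) stop_mircos("mircos_series_error", "a perturbation series needs m >= 2")
  if (identical(reference, "mean")) {
    ref <- colMeans(series$absorbance)
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != length(series$wavenumbers))
      stop_mircos("mircos_grid_error", "reference not on the series grid")
  }
  D <- sweep(series$absorbance, 2, ref)
  structure(list(D = unname(D), reference = ref, m = m,
                 wavenumbers = series$wavenumbers),
            class = "dynamic_spectra")
}

as_dynamic_matrix <- function(D) {
  if (inherits(D, "dynamic_spectra")) D$D else as.matrix(D)
}

#' Synchronous correlation map
#'
#' `Phi = t(D) %*% D / (m - 1)`: the covariance-like in-phase correlation of
#' intensity variations between every wavenumber pair. Symmetric with
#' nonnegative diagonal (the per-wavenumber variance when the reference is
#' the series mean).
#'
#' @param D a `dynamic_spectra` or an m x n dynamic-spectrum matrix.
#' @return an `n x n` matrix.
#' @export
synchronous_map <- function(D) {
  M <- as_dynamic_matrix(D)
  m <- nrow(M)
  if (m < 2) stop_mircos("mircos_series_error", "synchronous map needs m >= 2")
  crossprod(M) / (m - 1)
}

#' Asynchronous correlation map
#'
#' `Psi = t(D) %*% N %*% D / (m - 1)` with `N` the Hilbert-Noda matrix:
#' the out-of-phase (sequential) correlation. Antisymmetric with a zero
#' diagonal.
#'
#' @param D a `dynamic_spectra` or an m x n dynamic-spectrum matrix.
#' @return an `n x n` matrix.
#' @export
asynchronous_map <- function(D) {
  M <- as_dynamic_matrix(D)
  m <- nrow(M)
  if (m < 2) stop_mircos("mircos_series_error", "asynchronous map needs m >= 2")
  N <- hilbert_noda_matrix(m)
  crossprod(M, N %*% M) / (m - 1)
}

#' Integrated correlation map
#'
#' The elementwise product `I(v1, v2) = Phi(v1, v2) * Psi(v1, v2)`;
#' antisymmetric whenever `Phi` is symmetric and `Psi` antisymmetric.
#'
#' @param phi synchronous map; `psi` asynchronous map (same shape).
#' @param psi asynchronous map.
#' @return an `n x n` matrix.
#' @export
integrated_map <- function(phi, psi) {
  if (!all(dim(phi) == dim(psi)))
    stop_mircos("mircos_dim_error", "synchronous/asynchronous shapes differ")
  phi * psi
}

#' Per-sample correlation maps
#'
#' Builds one synchronous, asynchronous and integrated map per sample. In
#' `"replicate"` mode (default) the perturbation series of a sample is its r
#' repeated scans (m = r). The default centering policy `"none"` applies the
#' correlation equations directly to the raw intensities, so the synchronous
#' map is dominated by the outer product of the sample's mean spectrum (a
#' stable, composition-driven pattern) while the asynchronous map reflects
#' only the small scan-to-scan differences; `center = "mean"` subtracts the
#' within-series mean first, turning the synchronous map into the
#' within-sample scan covariance. In `"deviation"` mode the series is the
#' sample's records minus the set's global mean spectrum; with a single
#' record per sample only the synchronous map (an outer product) is defined
#' and `async`/`integrated` are `NULL`.
#'
#' @param x a `SpectraSet`.
#' @param mode `"replicate"` or `"deviation"`.
#' @param center `"none"` (raw intensities, default) or `"mean"`
#'   (within-series mean-centering); ignored in deviation mode, which centers
#'   on the global mean by construction.
#' @param downsample integer decimation factor applied to the wavenumber grid
#'   before map computation (every `downsample`-th point is kept).
#' @return named list (one element per sample) of lists with `sync`, `async`,
#'   `integrated`, `wavenumbers`, `sample_id`, `class`, `mode`.
#' @export
per_sample_maps <- function(x, mode = c("replicate", "deviation"),
                            center = c("none", "mean"), downsample = 4) {
  center <- match.arg(center)
  stopifnot(inherits(x, "SpectraSet"))
  mode <- match.arg(mode)
  downsample <- as.integer(downsample)
  if (downsample < 1) stop_mircos("mircos_parameter_error", "downsample must be >= 1")
  keep <- seq(1, length(x$wavenumbers), by = downsample)
  w <- x$wavenumbers[keep]

  if (mode == "replicate" && is.null(x$replicate_index))
    stop_mircos("mircos_mode_error",
                "replicate mode needs replicate scans (r >= 2) per sample")

  ids <- unique(x$sample_ids)
  global_mean <- colMeans(x$absorbance)[keep]
  out <- lapply(ids, function(sid) {
    rows <- which(x$sample_ids == sid)
    M <- x$absorbance[rows, keep, drop = FALSE]
    cl <- x$labels[rows[1]]
    if (mode == "replicate") {
      D <- if (center == "mean") sweep(M, 2, colMeans(M)) else M
      phi <- synchronous_map(D)
      psi <- asynchronous_map(D)
      ii <- integrated_map(phi, psi)
    } else {
      D <- sweep(M, 2, global_mean)
      if (nrow(D) >= 2) {
        phi <- synchronous_map(D)
        psi <- asynchronous_map(D)
        ii <- integrated_map(phi, psi)
      } else {
        phi <- crossprod(D)          # outer product of the single deviation
        psi <- NULL
        ii <- NULL
      }
    }
    list(sync = phi, async = psi, integrated = ii, wavenumbers = w,
         sample_id = sid, class = cl, mode = mode)
  })
  names(out) <- ids
  out
}
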