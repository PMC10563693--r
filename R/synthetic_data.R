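#' Default mid-infrared band table for a starchy plant powder
#'
#' Gaussian bands placed at the characteristic absorptions of a dried tuber
#' powder: carbohydrate C-O/C-C/C-O-H at 1014 cm^-1, phosphodiester bands
#' near 1220 and 1240 cm^-1, the lipid/protein CH2/CH3 composite over
#' 1300-1500 cm^-1, the amide I C=O at 1635 cm^-1, aliphatic C-H stretches in
#' 2800-3000 cm^-1 (2921 cm^-1 CH2), and the broad O-H/N-H stretch at
#' 3276 cm^-1. The two classes share every peak position and width and differ
#' only through per-class amplitude multipliers on a subset of bands, i.e.
#' the class effect is a change in absorbance, not in peak shape.
#'
#' @param contrast multiplier applied to the wild class on the discriminating
#'   bands (the cultivated class keeps multiplier 1). `contrast = 1` yields a
#'   null effect: identical class mean spectra in expectation.
#' @param classes the two class names (`c("wild", "cultivated")`).
#' @return a data.frame with one row per band: `center`, `width` (Gaussian
#'   sigma, cm^-1), `base_amplitude` (absorbance units) and one multiplier
#'   column per class (`mult_<class>`).
#' @export
default_band_table <- function(contrast = 1.5,
                               classes = c("wild", "cultivated")) {
  if (contrast <= 0) stop_mircos("mircos_config_error", "contrast must be > 0")
  bands <- data.frame(
    center = c(1014, 1220, 1240, 1340, 1410, 1460, 1635, 2850, 2921, 3276),
    width  = c(  18,   12,   10,   30,   35,   25,   25,   15,   20,   90),
    base_amplitude = c(1.00, 0.35, 0.30, 0.25, 0.30, 0.25, 0.55, 0.15, 0.25, 0.45)
  )
  # Bands whose absorbance differs between the classes (carbohydrate,
  # CH-bending, amide I, CH2 stretch, O-H/N-H); the rest are shared.
  discriminating <- bands$center %in% c(1014, 1340, 1460, 1635, 2921, 3276)
  bands[[paste0("mult_", classes[1])]] <- ifelse(discriminating, contrast, 1)
  bands[[paste0("mult_", classes[2])]] <- 1
  bands
}

#' Configuration for the synthetic two-class FT-MIR generator
#'
#' Defaults emulate the acquisition design of the authentication study the
#' package reproduces: 109 cultivated + 63 wild samples, 3 scans per sample,
#' a 4000-450 cm^-1 grid digitized at 2 cm^-1, additive linear baseline
#' drift, multiplicative scatter gain per scan, and iid Gaussian measurement
#' noise at 1% of the tallest band amplitude.
#'
#' @param n_per_class named integer vector, records per class.
#' @param grid `c(high, low, step)` in cm^-1 (descending storage).
#' @param peaks band table as from [default_band_table()].
#' @param noise_sd iid Gaussian noise sd, absorbance units.
#' @param baseline_offset,baseline_slope ranges `c(min, max)` of the additive
#'   baseline `offset + slope * wavenumber`, drawn per record.
#' @param scatter multiplicative gain range `c(min, max)`, drawn per record.
#' @param replicates scans per sample (r >= 1).
#' @param replicate_jitter_sd sd of a per-scan constant absorbance offset,
#'   emulating repositioning drift between repeated scans.
#' @param seed integer RNG seed.
#' @param classes the two class names.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(cultivated = 109, wild = 63),
                             grid = c(high = 4000, low = 450, step = 2),
                             peaks = default_band_table(),
                             noise_sd = 0.01,
                             baseline_offset = c(-0.02, 0.02),
                             baseline_slope = c(-5e-6, 5e-6),
                             scatter = c(0.95, 1.05),
                             replicates = 3,
                             replicate_jitter_sd = 0.002,
                             seed = 1,
                             classes = c("wild", "cultivated")) {
  if (length(n_per_class) != 2L || is.null(names(n_per_class)))
    stop_mircos("mircos_config_error", "n_per_class must name the two classes")
  if (!setequal(names(n_per_class), classes))
    stop_mircos("mircos_config_error", "n_per_class missing a class: ",
                paste(setdiff(classes, names(n_per_class)), collapse = ", "))
  if (any(n_per_class < 1)) stop_mircos("mircos_config_error", "counts must be >= 1")
  if (noise_sd < 0) stop_mircos("mircos_config_error", "noise_sd must be >= 0")
  if (any(scatter <= 0)) stop_mircos("mircos_config_error", "scatter gains must be > 0")
  if (replicates < 1) stop_mircos("mircos_config_error", "replicates must be >= 1")
  if (any(peaks$width <= 0) || any(peaks$base_amplitude < 0))
    stop_mircos("mircos_config_error", "peak widths must be > 0, amplitudes >= 0")
  structure(list(n_per_class = n_per_class, grid = grid, peaks = peaks,
                 noise_sd = noise_sd, baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, scatter = scatter,
                 replicates = as.integer(replicates),
                 replicate_jitter_sd = replicate_jitter_sd,
                 seed = as.integer(seed), classes = classes),
            class = "synthetic_config")
}

#' Noise-free class spectrum implied by a configuration
#' @param config a `synthetic_config`; `class_name` one of its classes.
#' @param class_name class whose clean spectrum to evaluate.
#' @return list with `wavenumbers` and `absorbance` (numeric vector).
#' @export
clean_class_spectrum <- function(config, class_name) {
  w <- grid_points(config$grid)
  mult <- config$peaks[[paste0("mult_", class_name)]]
  if (is.null(mult))
    stop_mircos("mircos_config_error", "band table lacks multipliers for class ",
                class_name)
  ab <- rep(0, length(w))
  for (i in seq_len(nrow(config$peaks))) {
    p <- config$peaks[i, ]
    ab <- ab + p$base_amplitude * mult[i] * exp(-(w - p$center)^2 / (2 * p$width^2))
  }
  list(wavenumbers = w, absorbance = ab)
}

grid_points <- function(grid) {
  seq(from = grid[["high"]], to = grid[["low"]], by = -abs(grid[["step"]]))
}

#' Generate a synthetic two-class FT-MIR SpectraSet
#'
#' Each record is `gain * clean + (offset + slope * wavenumber) + jitter +
#' noise`, where `clean` is the Gaussian band sum of the record's class; every
#' scan draws its own gain, baseline, jitter offset and iid noise, so the
#' replicate scans of a sample differ by scatter/baseline/noise only, exactly
#' the within-sample variation the correlation maps operate on. Deterministic
#' for a fixed `seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [spectra_set()] with `replicates` records per sample.
#' @export
generate_spectra <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- grid_points(config$grid)
  lo <- min(w); hi <- max(w)
  if (any(config$peaks$center < lo | config$peaks$center > hi))
    stop_mircos("mircos_config_error", "peak center outside the grid range")

  clean <- lapply(config$classes, function(cl) clean_class_spectrum(config, cl)$absorbance)
  names(clean) <- config$classes

  r <- config$replicates
  n_samples <- sum(config$n_per_class)
  n_rec <- n_samples * r
  ab <- matrix(0, n_rec, length(w))
  sample_ids <- character(n_rec)
  labels <- character(n_rec)
  rep_idx <- integer(n_rec)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  k <- 0L
  for (cl in names(config$n_per_class)) {
    for (i in seq_len(config$n_per_class[[cl]])) {
      sid <- sprintf("%s_%03d", cl, i)
      for (j in seq_len(r)) {
        k <- k + 1L
        gain <- runif(1, config$scatter[1], config$scatter[2])
        off <- runif(1, config$baseline_offset[1], config$baseline_offset[2])
        slp <- runif(1, config$baseline_slope[1], config$baseline_slope[2])
        jit <- if (config$replicate_jitter_sd > 0)
          rnorm(1, 0, config$replicate_jitter_sd) else 0
        noise <- if (config$noise_sd > 0) rnorm(length(w), 0, config$noise_sd) else 0
        ab[k, ] <- gain * clean[[cl]] + off + slp * w + jit + noise
        sample_ids[k] <- sid
        labels[k] <- cl
        rep_idx[k] <- j
      }
    }
  }
  spectra_set(w, ab, sample_ids, labels,
              replicate_index = if (r > 1L) rep_idx else NULL,
              classes = sort(config$classes))
}
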