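test_that("Hilbert-Noda matrix matches its closed form and is antisymmetric", {
  expect_equal(hilbert_noda_matrix(1), matrix(0, 1, 1))
  N3 <- rbind(c(0, 1 / pi, 1 / (2 * pi)),
              c(-1 / pi, 0, 1 / pi),
              c(-1 / (2 * pi), -1 / pi, 0))
  expect_equal(hilbert_noda_matrix(3), N3, tolerance = 1e-15)
  for (m in c(2, 5, 8)) {
    N <- hilbert_noda_matrix(m)
    expect_equal(N + t(N), matrix(0, m, m))
    expect_equal(diag(N), rep(0, m))
  }
  expect_error(hilbert_noda_matrix(0), class = "mircos_parameter_error")
})

two_record_set <- function(M, w = c(4000, 3998)) {
  spectra_set(w, M, paste0("s", seq_len(nrow(M))),
              rep(c("wild", "cultivated"), length.out = nrow(M)),
              classes = c("wild", "cultivated"))
}

test_that("dynamic spectra subtract the chosen reference", {
  same <- two_record_set(rbind(c(2, 5), c(2, 5)))
  expect_equal(dynamic_spectra(same)$D, matrix(0, 2, 2))

  x <- two_record_set(rbind(c(1, 3), c(3, 1)))
  d <- dynamic_spectra(x)
  expect_equal(d$reference, c(2, 2), ignore_attr = TRUE)
  expect_equal(d$D, rbind(c(-1, 1), c(1, -1)))
  expect_equal(colSums(d$D), c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)

  d0 <- dynamic_spectra(x, reference = c(0, 0))
  expect_equal(d0$D, rbind(c(1, 3), c(3, 1)))
  expect_error(dynamic_spectra(x, reference = c(0, 0, 0)),
               class = "mircos_grid_error")
})

test_that("synchronous map is the hand-computed cross product over m - 1", {
  D <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  expect_equal(synchronous_map(D), rbind(c(1, 0.5), c(0.5, 1)))
  expect_equal(synchronous_map(matrix(0, 3, 2)), matrix(0, 2, 2))

  # diagonal equals the per-wavenumber variance when centered on the mean
  set.seed(4)
  M <- matrix(rnorm(8 * 5), 8, 5)
  sp <- spectra_set(seq(4000, by = -2, length.out = 5), M,
                    paste0("s", 1:8), rep(c("wild", "cultivated"), 4),
                    classes = c("wild", "cultivated"))
  phi <- synchronous_map(dynamic_spectra(sp))
  expect_equal(diag(phi), apply(M, 2, var), ignore_attr = TRUE)
  expect_lt(max(abs(phi - t(phi))), 1e-10)
})

test_that("asynchronous map matches the m = 3 hand computation", {
  D <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  psi <- asynchronous_map(D)
  expect_equal(psi, rbind(c(0, 3 / (4 * pi)), c(-3 / (4 * pi), 0)),
               tolerance = 1e-12)
  # m = 2 with opposite rows cancels exactly
  d <- c(0.3, -1.2, 4)
  expect_equal(asynchronous_map(rbind(d, -d)), matrix(0, 3, 3),
               tolerance = 1e-12)
  # zero diagonal and antisymmetry for arbitrary D
  set.seed(7)
  A <- matrix(rnorm(6 * 4), 6, 4)
  psiA <- asynchronous_map(A)
  expect_equal(diag(psiA), rep(0, 4), tolerance = 1e-12)
  expect_equal(psiA + t(psiA), matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("integrated map is the elementwise product", {
  D <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  phi <- synchronous_map(D)
  psi <- asynchronous_map(D)
  ii <- integrated_map(phi, psi)
  expect_equal(ii, rbind(c(0, 3 / (8 * pi)), c(-3 / (8 * pi), 0)),
               tolerance = 1e-12)
  expect_equal(ii + t(ii), matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(integrated_map(phi, psi * 0), matrix(0, 2, 2))
  expect_error(integrated_map(phi, matrix(0, 3, 3)),
               class = "mircos_dim_error")
})

test_that("maps scale quadratically (and integrated quartically) in intensity", {
  set.seed(11)
  D <- matrix(rnorm(5 * 6), 5, 6)
  c2 <- 3
  expect_equal(synchronous_map(c2 * D), c2^2 * synchronous_map(D))
  expect_equal(asynchronous_map(c2 * D), c2^2 * asynchronous_map(D))
  expect_equal(integrated_map(synchronous_map(c2 * D), asynchronous_map(c2 * D)),
               c2^4 * integrated_map(synchronous_map(D), asynchronous_map(D)))
})

test_that("wavenumber permutation permutes map rows and columns consistently", {
  set.seed(12)
  D <- matrix(rnorm(4 * 5), 4, 5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(synchronous_map(D[, perm]), synchronous_map(D)[perm, perm])
  expect_equal(asynchronous_map(D[, perm]), asynchronous_map(D)[perm, perm])
})

test_that("per-sample maps produce three maps per sample with expected structure", {
  sp <- tiny_spectra()
  maps <- per_sample_maps(sp, downsample = 8)
  expect_length(maps, 20)
  n_maps <- sum(vapply(maps, function(m)
    sum(!is.null(m$sync), !is.null(m$async), !is.null(m$integrated)), 0L))
  expect_equal(n_maps, 60)   # 3 x n_samples
  m1 <- maps[[1]]
  expect_equal(dim(m1$sync), rep(length(m1$wavenumbers), 2))
  expect_lt(max(abs(m1$sync - t(m1$sync))), 1e-10)
  expect_true(all(diag(m1$sync) >= -1e-12))
  expect_equal(diag(m1$async), rep(0, nrow(m1$async)), tolerance = 1e-12)
  expect_equal(m1$integrated, m1$sync * m1$async)
})

test_that("decimation arithmetic: a 1776-point grid at factor 4 gives 444", {
  cfg <- tiny_config(n_per_class = c(cultivated = 1, wild = 1),
                     grid = c(high = 4000, low = 450, step = 2))
  sp <- generate_spectra(cfg)
  expect_length(sp$wavenumbers, 1776)
  maps <- per_sample_maps(sp, downsample = 4)
  expect_equal(dim(maps[[1]]$sync), c(444, 444))
})

test_that("identical replicates give zero maps under mean-centering", {
  cfg <- tiny_config(n_per_class = c(cultivated = 2, wild = 2),
                     noise_sd = 0, scatter = c(1, 1),
                     baseline_offset = c(0, 0), baseline_slope = c(0, 0),
                     replicate_jitter_sd = 0)
  sp <- generate_spectra(cfg)
  maps <- per_sample_maps(sp, center = "mean", downsample = 8)
  expect_equal(max(abs(maps[[1]]$sync)), 0)
  expect_equal(max(abs(maps[[1]]$async)), 0)
  # while the raw-intensity policy keeps the composition signal
  raw_maps <- per_sample_maps(sp, downsample = 8)
  expect_gt(max(abs(raw_maps[[1]]$sync)), 0.1)
})

test_that("deviation mode with single records yields sync-only maps", {
  sp <- average_replicates(tiny_spectra())
  maps <- per_sample_maps(sp, mode = "deviation", downsample = 8)
  expect_null(maps[[1]]$async)
  expect_null(maps[[1]]$integrated)
  expect_false(is.null(maps[[1]]$sync))
  expect_error(per_sample_maps(sp, mode = "replicate"),
               class = "mircos_mode_error")
})
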