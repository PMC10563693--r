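make_set <- function(M, w = NULL) {
  n <- nrow(M)
  w <- w %||% seq(from = 4000, by = -2, length.out = ncol(M))
  mircos::spectra_set(w, M, paste0("s", seq_len(n)),
                      rep(c("wild", "cultivated"), length.out = n),
                      classes = c("wild", "cultivated"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SNV centers and scales each record (sample sd) and is idempotent", {
  x <- make_set(rbind(c(1, 2, 3), c(10, 20, 60)))
  out <- snv(x)
  expect_equal(out$absorbance[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(rowMeans(out$absorbance), c(0, 0), ignore_attr = TRUE)
  expect_equal(apply(out$absorbance, 1, sd), c(1, 1), ignore_attr = TRUE)
  expect_equal(snv(out)$absorbance, out$absorbance, tolerance = 1e-12)

  expect_error(snv(make_set(rbind(c(5, 5, 5), c(1, 2, 3)))),
               class = "mircos_degenerate_error")
})

test_that("MSC exactly inverts affine distortions of its reference", {
  set.seed(1)
  ref <- exp(-seq(-3, 3, length.out = 50)^2)
  x <- make_set(rbind(2 * ref + 1, ref, -0.5 * ref + 0.2))
  out <- msc(x, reference = ref)
  for (i in 1:3)
    expect_equal(out$absorbance[i, ], ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("MSC recovers the clean class spectrum from scatter and offsets", {
  cfg <- tiny_config(n_per_class = c(cultivated = 6, wild = 6),
                     noise_sd = 0, scatter = c(0.8, 1.2),
                     baseline_offset = c(-0.05, 0.05),
                     baseline_slope = c(0, 0),
                     replicates = 1, replicate_jitter_sd = 0)
  sp <- generate_spectra(cfg)
  cult <- subset_records(sp, sp$labels == "cultivated")
  clean <- clean_class_spectrum(cfg, "cultivated")$absorbance
  out <- msc(cult, reference = clean)
  for (i in seq_len(n_records(out)))
    expect_equal(out$absorbance[i, ], clean, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("Savitzky-Golay is exact on polynomials, edges included", {
  w <- seq(100, 1, by = -1)
  cubic <- 2 + 0.5 * w - 0.01 * w^2 + 1e-4 * w^3
  x <- make_set(rbind(cubic), w)
  sm <- savitzky_golay(x, window = 15, polyorder = 3, deriv_order = 0)
  expect_equal(sm$absorbance[1, ], cubic, tolerance = 1e-8,
               ignore_attr = TRUE)

  quad <- make_set(rbind(w^2), w)
  d1 <- savitzky_golay(quad, 15, 3, 1)
  interior <- 8:93
  expect_equal(d1$absorbance[1, interior], (2 * w)[interior],
               tolerance = 1e-9, ignore_attr = TRUE)

  line <- make_set(rbind(3 * w + 7), w)
  d2 <- savitzky_golay(line, 15, 3, 2)
  expect_equal(max(abs(d2$absorbance)), 0, tolerance = 1e-9)
})

test_that("derivatives are grid-direction invariant physical derivatives", {
  w_desc <- seq(200, 2, by = -2)
  x_desc <- make_set(rbind(w_desc^2), w_desc)
  d_desc <- savitzky_golay(x_desc, 15, 3, 1)
  w_asc <- rev(w_desc)
  x_asc <- make_set(rbind(w_asc^2), w_asc)
  d_asc <- savitzky_golay(x_asc, 15, 3, 1)
  i <- 20:80
  expect_equal(d_desc$absorbance[1, i], 2 * w_desc[i], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(d_asc$absorbance[1, i], 2 * w_asc[i], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("filter parameter validation", {
  x <- make_set(rbind(rnorm(50)))
  expect_error(savitzky_golay(x, window = 14, polyorder = 3),
               class = "mircos_parameter_error")
  expect_error(savitzky_golay(x, window = 3, polyorder = 3),
               class = "mircos_parameter_error")
  expect_error(savitzky_golay(x, window = 15, polyorder = 3, deriv_order = 4),
               class = "mircos_parameter_error")
})

test_that("chains compose left to right and never touch metadata", {
  sp <- tiny_spectra()
  one <- apply_chain(sp, "SNV")
  expect_equal(one$absorbance, snv(sp)$absorbance)

  chained <- apply_chain(sp, "SNV+2D")
  manual <- savitzky_golay(snv(sp), 15, 3, 2)
  expect_equal(chained$absorbance, manual$absorbance)

  for (chain in c("RAW", "1D", "2D", "SG", "SNV", "MSC")) {
    out <- apply_chain(sp, chain)
    expect_identical(out$sample_ids, sp$sample_ids)
    expect_identical(out$labels, sp$labels)
    expect_equal(n_records(out), n_records(sp))
  }
  expect_error(apply_chain(sp, "OSC"), class = "mircos_parameter_error")
})

test_that("a frozen MSC reference is applied to held-out records without refit", {
  sp <- average_replicates(tiny_spectra())
  split <- stratified_split(sp)
  train <- subset_samples(sp, split$train_ids)
  test <- subset_samples(sp, split$test_ids)
  ref <- msc_reference(train)
  held <- subset_samples(test, test$sample_ids[1])
  a <- msc(held, reference = ref)$absorbance
  # transforming the record alongside others must give the same result:
  b <- msc(test, reference = ref)$absorbance[1, , drop = FALSE]
  expect_equal(a, b, ignore_attr = TRUE)
  # while refitting the reference on the test set would not
  c <- msc(test)$absorbance[1, , drop = FALSE]
  expect_false(isTRUE(all.equal(a, c, check.attributes = FALSE)))
})
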