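# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A small clean two-class configuration on a coarse grid: fast everywhere.
tiny_config <- function(seed = 42, ...) {
  args <- list(
    n_per_class = c(cultivated = 12, wild = 8),
    grid = c(high = 4000, low = 450, step = 8),
    seed = seed)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(synthetic_config, args)
}

tiny_spectra <- function() fixture("tiny_spectra", function() {
  generate_spectra(tiny_config())
})

# A rendered synchronous-map image dataset over the tiny spectra.
tiny_dataset <- function() fixture("tiny_dataset", function() {
  maps <- per_sample_maps(tiny_spectra(), downsample = 8)
  build_image_dataset(
    maps, file.path(tempdir(), "mircos_tiny_ds"),
    counts = c(train = 10, test = 5, ev = 5), seed = 5,
    config = render_config(image_size = 64),
    categories = "synchronous")
})

# Deterministic well-separated two-cluster data for classifier contracts.
two_clusters <- function(n_per = 20, p = 12, gap = 6, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = gap / sqrt(p)), n_per))
  y <- rep(c("cultivated", "wild"), each = n_per)
  list(X = X, y = y)
}

# Independent brute-force maxmin greedy oracle used to validate the
# Kennard-Stone implementation.
maxmin_oracle <- function(X, n_select) {
  d <- as.matrix(dist(X))
  n <- nrow(X)
  pairs <- which(d == max(d), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  sel <- as.integer(pairs[1, ])
  while (length(sel) < n_select) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(i) min(d[i, sel]), 0)
    best <- max(mind)
    sel <- c(sel, rest[which(mind == best)[1]])
  }
  sel
}

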