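#' Spectral data container
#'
#' A `SpectraSet` couples a wavenumber grid (cm^-1, strictly monotonic with a
#' constant step, conventionally descending as acquired, e.g. 4000 to 450)
#' with an absorbance matrix (one row per record), per-record sample
#' identifiers, two-class labels, and an optional replicate index marking
#' repeated scans of the same sample.
#'
#' @param wavenumbers numeric grid in cm^-1, strictly monotonic, constant step.
#' @param absorbance numeric matrix, `n_records x length(wavenumbers)`.
#' @param sample_ids character vector of sample keys, one per record. Several
#'   records may share a `sample_id` when `replicate_index` is given.
#' @param labels class name per record; values must come from `classes`.
#' @param replicate_index optional integer `1..r` per record; every sample
#'   must then carry the same replicate count `r >= 2`.
#' @param classes the two class names; defaults to the sorted unique labels.
#' @return an object of class `SpectraSet`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids, labels,
                        replicate_index = NULL, classes = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  labels <- as.character(labels)
  sample_ids <- as.character(sample_ids)
  classes <- classes %||% sort(unique(labels))

  n <- nrow(absorbance)
  if (length(wavenumbers) != ncol(absorbance))
    stop_mircos("mircos_dim_error", "absorbance has ", ncol(absorbance),
                " columns but the grid has ", length(wavenumbers), " points")
  if (length(sample_ids) != n || length(labels) != n)
    stop_mircos("mircos_dim_error", "sample_ids/labels length must equal record count")
  if (anyNA(absorbance) || anyNA(wavenumbers))
    stop_mircos("mircos_value_error", "missing values are not allowed")
  validate_grid(wavenumbers)
  if (length(classes) != 2L && n > 0L)
    stop_mircos("mircos_class_error", "exactly two classes are required, got: ",
                paste(classes, collapse = ", "))
  if (!all(labels %in% classes))
    stop_mircos("mircos_class_error", "labels outside the configured classes: ",
                paste(setdiff(labels, classes), collapse = ", "))

  if (!is.null(replicate_index)) {
    replicate_index <- as.integer(replicate_index)
    if (length(replicate_index) != n)
      stop_mircos("mircos_dim_error", "replicate_index length must equal record count")
    r <- table(sample_ids)
    if (length(unique(as.integer(r))) != 1L || r[1] < 2L)
      stop_mircos("mircos_replicate_error",
                  "every sample must have the same replicate count r >= 2")
    rec_ids <- paste0(sample_ids, "#", replicate_index)
  } else {
    if (anyDuplicated(sample_ids))
      stop_mircos("mircos_key_error", "duplicated sample_id without replicate markers: ",
                  sample_ids[duplicated(sample_ids)][1])
    rec_ids <- sample_ids
  }
  if (anyDuplicated(rec_ids))
    stop_mircos("mircos_key_error", "duplicated record id: ", rec_ids[duplicated(rec_ids)][1])
  rownames(absorbance) <- rec_ids

  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_ids = sample_ids, labels = labels,
         replicate_index = replicate_index, classes = classes),
    class = "SpectraSet")
}

validate_grid <- function(w) {
  if (length(w) < 2L) return(invisible(w))
  d <- diff(w)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop_mircos("mircos_grid_error", "wavenumber grid is not strictly monotonic")
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1]))
    stop_mircos("mircos_grid_error", "wavenumber grid step is not constant")
  invisible(w)
}

#' @export
print.SpectraSet <- function(x, ...) {
  r <- if (is.null(x$replicate_index)) 1L else max(x$replicate_index)
  cat(sprintf("SpectraSet: %d records (%d samples x %d scans), %d points [%g..%g cm^-1]\n",
              n_records(x), length(unique(x$sample_ids)), r,
              length(x$wavenumbers), x$wavenumbers[1],
              x$wavenumbers[length(x$wavenumbers)]))
  print(table(sample_labels(x)))
  invisible(x)
}

#' @rdname spectra_set
#' @param x a `SpectraSet`.
#' @export
n_records <- function(x) nrow(x$absorbance)

# One label per distinct sample (records of one sample always agree).
sample_labels <- function(x) {
  ids <- unique(x$sample_ids)
  x$labels[match(ids, x$sample_ids)]
}

#' Subset a SpectraSet by record index
#' @param x a `SpectraSet`; `i` record indices (logical or integer).
#' @param keep_replicates if `TRUE` and replicates are present, all records of
#'   the touched samples are kept so replicates travel together.
#' @export
subset_records <- function(x, i, keep_replicates = TRUE) {
  idx <- seq_len(n_records(x))[i]
  if (!is.null(x$replicate_index) && keep_replicates) {
    ids <- unique(x$sample_ids[idx])
    idx <- which(x$sample_ids %in% ids)
  }
  rep_idx <- if (is.null(x$replicate_index)) NULL else x$replicate_index[idx]
  spectra_set(x$wavenumbers, x$absorbance[idx, , drop = FALSE],
              x$sample_ids[idx], x$labels[idx], rep_idx, classes = x$classes)
}

#' Subset a SpectraSet by sample id
#' @param x a `SpectraSet`; `ids` sample ids to keep.
#' @export
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, x$sample_ids)
  if (length(missing))
    stop_mircos("mircos_key_error", "unknown sample ids: ",
                paste(head(missing, 3), collapse = ", "))
  subset_records(x, x$sample_ids %in% ids, keep_replicates = FALSE)
}

#' Average replicate scans into one spectrum per sample
#'
#' Mirrors the spectrometer-side convention of averaging repeated scans of a
#' sample into its working spectrum. A set without replicates is returned
#' unchanged.
#' @param x a `SpectraSet`.
#' @return a `SpectraSet` with one record per sample and no replicate index.
#' @export
average_replicates <- function(x) {
  if (is.null(x$replicate_index)) return(x)
  ids <- unique(x$sample_ids)
  acc <- rowsum(x$absorbance, group = x$sample_ids, reorder = FALSE)
  cnt <- as.vector(table(factor(x$sample_ids, levels = rownames(acc))))
  avg <- acc / cnt
  ord <- match(ids, rownames(avg))
  spectra_set(x$wavenumbers, avg[ord, , drop = FALSE], ids,
              x$labels[match(ids, x$sample_ids)], classes = x$classes)
}

#' Read spectra from a wide CSV plus a label sidecar
#'
#' The wide CSV holds the wavenumber grid in its first column and one column
#' per record; replicate records are named `sample_id#k`. The sidecar is a
#' two-column CSV `sample_id,class`. Records without a label are rejected.
#'
#' @param path path to the wide spectral CSV.
#' @param labels_path path to the `sample_id,class` sidecar CSV.
#' @param classes optional explicit class pair.
#' @return a `SpectraSet`.
#' @export
read_spectra_csv <- function(path, labels_path, classes = NULL) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 1L) stop_mircos("mircos_parse_error", "empty spectral table")
  num <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad))
      stop_mircos("mircos_parse_error", sprintf(
        "non-numeric cell at row %d, column '%s': '%s'",
        bad[1], names(raw)[j], raw[bad[1], j]))
    num[, j] <- v
  }
  w <- num[, 1]
  validate_grid(w)

  rec_names <- names(raw)[-1]
  has_rep <- grepl("#[0-9]+$", rec_names)
  if (any(has_rep) && !all(has_rep))
    stop_mircos("mircos_key_error",
                "mix of replicate-suffixed and plain record names")
  if (any(has_rep)) {
    sample_ids <- sub("#[0-9]+$", "", rec_names)
    rep_idx <- as.integer(sub("^.*#", "", rec_names))
  } else {
    sample_ids <- rec_names
    rep_idx <- NULL
  }

  lab_tab <- read.csv(labels_path, check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(lab_tab)))
    stop_mircos("mircos_parse_error",
                "label sidecar must have columns sample_id,class")
  if (anyDuplicated(lab_tab$sample_id))
    stop_mircos("mircos_key_error", "duplicated sample_id in label sidecar")
  m <- match(sample_ids, lab_tab$sample_id)
  if (anyNA(m))
    stop_mircos("mircos_key_error", "records lacking a label: ",
                paste(head(unique(sample_ids[is.na(m)]), 3), collapse = ", "))

  absorbance <- t(num[, -1, drop = FALSE])
  if (ncol(raw) == 1L) absorbance <- matrix(0, 0, nrow(raw))
  spectra_set(w, absorbance, sample_ids, lab_tab$class[m], rep_idx,
              classes = classes)
}

#' Write a SpectraSet as a wide CSV (17 significant digits)
#'
#' The written file round-trips through [read_spectra_csv()] losslessly at
#' double precision, and writing is byte-deterministic.
#' @param x a `SpectraSet`; `path` output CSV path.
#' @param path output path for the wide spectral CSV.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  fmt <- function(v) sprintf("%.17g", v)
  header <- paste(c("wavenumber", rownames(x$absorbance)), collapse = ",")
  body <- vapply(seq_along(x$wavenumbers), function(i) {
    paste(c(fmt(x$wavenumbers[i]), fmt(x$absorbance[, i])), collapse = ",")
  }, character(1))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_mircos("mircos_io_error", "cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write the label sidecar for a SpectraSet
#' @param x a `SpectraSet`; `path` output CSV path.
#' @param path output path for the `sample_id,class` CSV.
#' @export
write_labels_csv <- function(x, path) {
  ids <- unique(x$sample_ids)
  df <- data.frame(sample_id = ids, class = x$labels[match(ids, x$sample_ids)])
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_mircos("mircos_io_error", "cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c("sample_id,class", paste(df$sample_id, df$class, sep = ",")), con)
  invisible(path)
}
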