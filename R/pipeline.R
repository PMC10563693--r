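#' Experiment configuration
#'
#' Bundles every stage's settings behind one object with two presets:
#' `"full"`, the full-scale reference design (109 + 63 samples, 3 scans each,
#' 4000-450 cm^-1 at 2 cm^-1, nine preprocessing chains, 84/36/52 image
#' partition, 200 permutations, 46 epochs, 224 px images), and `"tiny"`, a
#' minutes-scale smoke design (20 samples, coarser grid, 64 px images, small
#' network) exercising every stage end to end.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param seed master seed; stage seeds are derived from it deterministically
#'   so stages can be rerun in isolation.
#' @param out_dir output directory for artifacts.
#' @param ... named overrides of any config element (`synthetic`, `chains`,
#'   `split_fraction`, `plsda`, `svm`, `cos`, `render`, `partition_counts`,
#'   `cnn`).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("tiny", "full"), seed = 1,
                              out_dir = tempfile("mircos_"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "full") {
    list(
      synthetic = synthetic_config(seed = derive_seed(seed, "synthetic")),
      chains = chain_names(),
      split_fraction = 0.7,
      plsda = list(n_components = 2, cv_folds = 7, n_permutations = 200),
      svm = list(c_grid = 2^(-10:20), g_grid = 2^(-20:4), cv_folds = 5),
      cos = list(mode = "replicate", downsample = 4),
      render = render_config(image_size = 224),
      partition_counts = c(train = 84, test = 36, ev = 52),
      cnn = list(epochs = 46, arch = resnet_spec(), lr = 1e-3,
                 batch_size = 16, early_stop = FALSE,
                 categories = c("synchronous", "asynchronous", "integrated")))
  } else {
    list(
      synthetic = synthetic_config(
        n_per_class = c(cultivated = 12, wild = 8),
        grid = c(high = 4000, low = 450, step = 8),
        seed = derive_seed(seed, "synthetic")),
      chains = c("RAW", "2D", "SNV"),
      split_fraction = 0.7,
      plsda = list(n_components = 2, cv_folds = 5, n_permutations = 20),
      svm = list(c_grid = 2^seq(-2, 6, 2), g_grid = 2^seq(-10, -2, 2),
                 cv_folds = 3),
      cos = list(mode = "replicate", downsample = 4),
      render = render_config(image_size = 64),
      partition_counts = c(train = 10, test = 5, ev = 5),
      cnn = list(epochs = 5, arch = resnet_spec(c(8, 16), 1), lr = 1e-3,
                 batch_size = 8, early_stop = FALSE,
                 categories = "synchronous"))
  }
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$preset <- preset
  base$seed <- as.integer(seed)
  base$out_dir <- out_dir
  structure(base, class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized top-level keys: `preset`, `seed`, `out_dir`, plus any
#' [experiment_config()] element; `synthetic` sub-keys are passed to
#' [synthetic_config()] and `render` sub-keys to [render_config()].
#'
#' @param path YAML file path.
#' @param out_dir optional output directory override.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list(preset = y$preset %||% "tiny", seed = y$seed %||% 1)
  args$out_dir <- out_dir %||% y$out_dir %||% tempfile("mircos_")
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    if (!is.null(sy$n_per_class)) sy$n_per_class <- unlist(sy$n_per_class)
    if (!is.null(sy$grid)) sy$grid <- unlist(sy$grid)
    args$synthetic <- do.call(synthetic_config, sy)
  }
  if (!is.null(y$render)) args$render <- do.call(render_config, y$render)
  for (nm in intersect(names(y), c("chains", "split_fraction", "plsda",
                                   "svm", "cos", "partition_counts", "cnn")))
    args[[nm]] <- y[[nm]]
  do.call(experiment_config, args)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run the full authentication experiment
#'
#' Simulate two-class spectra, split them by stratified Kennard-Stone, fit
#' PLS-DA (with permutation diagnostics) and grid-searched RBF-SVM under
#' every configured preprocessing chain, build per-sample correlation maps,
#' render them, train the residual CNN per configured image category, and
#' score everything with the confusion-metric layer. All tables are written
#' as CSV plus one machine-readable JSON report; the run is reproducible
#' from the configuration alone.
#'
#' @param config an [experiment_config()].
#' @return the report list, invisibly; artifacts under `config$out_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(preset = config$preset, seed = config$seed,
                 config_digest = config_digest(config))

  log_stage("simulate", "generating synthetic spectra")
  spectra <- generate_spectra(config$synthetic)
  write_spectra_csv(spectra, file.path(out, "spectra.csv"))
  write_labels_csv(spectra, file.path(out, "labels.csv"))
  avg <- average_replicates(spectra)

  log_stage("split", "stratified Kennard-Stone")
  split <- stratified_split(avg, fraction = config$split_fraction)
  write_split_csv(split, file.path(out, "split.csv"))
  report$split <- list(
    per_class_counts = as.list(as.data.frame(split$per_class_counts)),
    n_train = length(split$train_ids), n_test = length(split$test_ids))

  Xtr_raw <- subset_samples(avg, split$train_ids)
  Xte_raw <- subset_samples(avg, split$test_ids)

  log_stage("pca", "exploratory PCA on raw spectra")
  pca <- pca_fit(avg$absorbance, k = 2)
  report$pca <- list(explained_variance_ratio = pca$explained_variance_ratio)

  log_stage("chemometrics", paste(length(config$chains), "chains"))
  t1 <- list(); t2 <- list(); t3 <- list()
  for (chain in config$chains) {
    ref <- msc_reference(Xtr_raw)
    Xtr <- apply_chain(Xtr_raw, chain, msc_ref = ref)
    Xte <- apply_chain(Xte_raw, chain, msc_ref = ref)

    pls <- plsda_fit(Xtr$absorbance, Xtr$labels,
                     n_components = config$plsda$n_components,
                     cv_folds = config$plsda$cv_folds)
    ev <- plsda_evaluate(pls, Xte$absorbance, Xte$labels)
    perm <- plsda_permutation_test(
      Xtr$absorbance, Xtr$labels,
      n_permutations = config$plsda$n_permutations,
      n_components = config$plsda$n_components,
      cv_folds = config$plsda$cv_folds,
      seed = derive_seed(config$seed, paste0("perm_", chain)))
    t1[[chain]] <- data.frame(
      preprocessing = chain,
      acc_train = 100 * pls$metrics$acc_train,
      acc_test = 100 * ev$acc_test,
      RMSEE = pls$metrics$RMSEE, RMSECV = pls$metrics$RMSECV,
      RMSEP = ev$RMSEP, R2 = pls$metrics$R2Y, Q2 = pls$metrics$Q2,
      q2_intercept = perm$q2_intercept, overfit = perm$overfit_flag)

    sv <- svm_grid_search(Xtr$absorbance, Xtr$labels,
                          c_grid = config$svm$c_grid,
                          g_grid = config$svm$g_grid,
                          cv_folds = config$svm$cv_folds,
                          seed = derive_seed(config$seed, paste0("svm_", chain)))
    sv_pred <- svm_predict(sv, Xte$absorbance)
    sv_counts <- confusion_counts(Xte$labels, sv_pred)
    sv_tr_acc <- mean(svm_predict(sv, Xtr$absorbance) == Xtr$labels)
    t2[[chain]] <- data.frame(
      preprocessing = chain, c = sv$best$c, g = sv$best$g,
      acc_train = 100 * sv_tr_acc,
      acc_test = 100 * mean(sv_pred == Xte$labels))

    pls_m <- ev$metrics
    sv_m <- confusion_metrics(sv_counts)
    t3[[chain]] <- data.frame(
      preprocessing = rep(chain, 2), model = c("PLS-DA", "SVM"),
      sen = c(pls_m$sen, sv_m$sen), spe = c(pls_m$spe, sv_m$spe),
      eff = c(pls_m$eff, sv_m$eff), acc = c(pls_m$acc, sv_m$acc))
  }
  table1 <- do.call(rbind, t1); rownames(table1) <- NULL
  table2 <- do.call(rbind, t2); rownames(table2) <- NULL
  table3 <- do.call(rbind, t3); rownames(table3) <- NULL
  write.csv(table1, file.path(out, "table1_plsda.csv"), row.names = FALSE)
  write.csv(table2, file.path(out, "table2_svm.csv"), row.names = FALSE)
  write.csv(table3, file.path(out, "table3_comparison.csv"), row.names = FALSE)
  report$plsda <- table1
  report$svm <- table2
  report$comparison <- table3

  log_stage("cosmap", "per-sample correlation maps")
  maps <- per_sample_maps(spectra, mode = config$cos$mode,
                          downsample = config$cos$downsample)
  log_stage("render", "rendering surface images")
  dataset <- build_image_dataset(
    maps, file.path(out, "images"), counts = config$partition_counts,
    seed = derive_seed(config$seed, "partition"), config = config$render,
    categories = config$cnn$categories)
  report$images <- list(
    n_images = nrow(dataset$manifest),
    per_category = as.list(table(dataset$manifest$category)),
    roles = as.list(config$partition_counts))

  t4 <- list()
  for (cat in config$cnn$categories) {
    log_stage("train-cnn", cat)
    model <- train_classifier(
      dataset, category = cat, epochs = config$cnn$epochs,
      seed = derive_seed(config$seed, paste0("cnn_", cat)),
      arch = config$cnn$arch, lr = config$cnn$lr,
      batch_size = config$cnn$batch_size,
      early_stop = isTRUE(config$cnn$early_stop))
    ev_tr <- evaluate_classifier(model, dataset, "train")
    ev_te <- evaluate_classifier(model, dataset, "test")
    ev_ev <- evaluate_classifier(model, dataset, "ev")
    utils::write.csv(model$history,
                     file.path(out, paste0("cnn_history_", cat, ".csv")),
                     row.names = FALSE)
    t4[[cat]] <- data.frame(
      category = cat, epochs = nrow(model$history),
      acc_train = 100 * ev_tr$metrics$acc, acc_test = 100 * ev_te$metrics$acc,
      acc_ev = 100 * ev_ev$metrics$acc, loss = ev_ev$loss,
      sen = ev_ev$metrics$sen, spe = ev_ev$metrics$spe,
      eff = ev_ev$metrics$eff)
  }
  table4 <- do.call(rbind, t4); rownames(table4) <- NULL
  write.csv(table4, file.path(out, "table4_cnn.csv"), row.names = FALSE)
  report$cnn <- table4

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_stage("report", "written to ", file.path(out, "report.json"))
  invisible(report)
}

config_digest <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "\n")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
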