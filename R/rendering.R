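#' Rendering configuration for correlation-map surface images
#'
#' @param image_size square image side in pixels (>= 32).
#' @param colormap palette name passed to [grDevices::hcl.colors()].
#' @param elevation viewing elevation in degrees, 0..90.
#' @param azimuth viewing azimuth in degrees, -180..180.
#' @param format `"png"` (byte-deterministic, default) or `"jpeg"`.
#' @param quality JPEG quality 1..100 (ignored for PNG).
#' @param decorations draw axes/box when `TRUE` (off by default so the
#'   classifier sees only the surface).
#' @param autoscale scale the intensity axis to each map's own min/max
#'   (`TRUE`, default) or to a fixed `zlim`.
#' @param zlim fixed intensity limits when `autoscale = FALSE`.
#' @return a list of class `render_config`.
#' @export
render_config <- function(image_size = 224, colormap = "Viridis",
                          elevation = 30, azimuth = -60,
                          format = c("png", "jpeg"), quality = 95,
                          decorations = FALSE, autoscale = TRUE, zlim = NULL) {
  format <- match.arg(format)
  if (image_size < 32) stop_mircos("mircos_parameter_error", "image_size must be >= 32")
  if (elevation < 0 || elevation > 90)
    stop_mircos("mircos_parameter_error", "elevation must be in [0, 90]")
  if (azimuth < -180 || azimuth > 180)
    stop_mircos("mircos_parameter_error", "azimuth must be in [-180, 180]")
  if (format == "jpeg" && !requireNamespace("jpeg", quietly = TRUE))
    stop_mircos("mircos_parameter_error", "JPEG output needs the 'jpeg' package")
  structure(list(image_size = as.integer(image_size), colormap = colormap,
                 elevation = elevation, azimuth = azimuth, format = format,
                 quality = quality, decorations = decorations,
                 autoscale = autoscale, zlim = zlim),
            class = "render_config")
}

#' Render a correlation map as a 3-D surface image
#'
#' Draws the map as a perspective surface over the wavenumber x wavenumber
#' plane, facets colored by height, and writes it to `path`. Rendering is
#' pure: the same map and configuration always produce the same image
#' (identical bytes for PNG). A constant map renders as a flat surface at
#' the colormap midpoint.
#'
#' @param map numeric matrix (a `sync`/`async`/`integrated` component).
#' @param path output image path.
#' @param config a [render_config()].
#' @return `path`, invisibly.
#' @export
render_surface <- function(map, path, config = render_config()) {
  map <- as.matrix(map)
  if (any(!is.finite(map)))
    stop_mircos("mircos_render_error", "map contains non-finite values")
  n <- nrow(map)
  if (n < 2 || ncol(map) < 2)
    stop_mircos("mircos_render_error", "map must be at least 2 x 2")

  if (config$autoscale || is.null(config$zlim)) {
    zlim <- range(map)
  } else {
    zlim <- config$zlim
  }
  pal <- grDevices::hcl.colors(256, config$colormap)
  facet <- (map[-1, -1] + map[-n, -1] + map[-1, -ncol(map)] +
              map[-n, -ncol(map)]) / 4
  if (zlim[1] == zlim[2]) {
    zlim <- zlim + c(-1, 1)
    cols <- matrix(pal[128], n - 1, ncol(map) - 1)
  } else {
    idx <- pmin(256, pmax(1, 1 + floor((facet - zlim[1]) / diff(zlim) * 255)))
    cols <- matrix(pal[idx], n - 1, ncol(map) - 1)
  }

  if (config$format == "png") {
    grDevices::png(path, width = config$image_size, height = config$image_size,
                   type = "cairo")
  } else {
    grDevices::jpeg(path, width = config$image_size, height = config$image_size,
                    quality = config$quality, type = "cairo")
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), bg = "white")
  graphics::persp(x = seq_len(n), y = seq_len(ncol(map)), z = map,
                  zlim = zlim, col = cols, border = NA,
                  theta = config$azimuth, phi = config$elevation,
                  expand = 0.55, box = config$decorations,
                  axes = config$decorations)
  invisible(path)
}

#' Stratified random role assignment
#'
#' Assigns each sample to one of the roles `train`/`test`/`ev` so that role
#' sizes match `counts` exactly and each class is represented in each role
#' proportionally to its global share (largest-remainder rounding, within
#' one sample of exact proportionality). One draw per seed; all image
#' categories share the assignment.
#'
#' @param sample_ids character vector of sample ids.
#' @param labels class per sample.
#' @param counts named integer vector `c(train, test, ev)` summing to the
#'   sample count.
#' @param seed integer RNG seed.
#' @return data.frame `sample_id`, `class`, `role`.
#' @export
partition_roles <- function(sample_ids, labels,
                            counts = c(train = 84, test = 36, ev = 52),
                            seed = 1) {
  n <- length(sample_ids)
  if (is.null(names(counts))) names(counts) <- c("train", "test", "ev")
  if (sum(counts) != n)
    stop_mircos("mircos_partition_error", "counts sum to ", sum(counts),
                " but there are ", n, " samples")
  if (any(counts[c("train", "test")] <= 0))
    stop_mircos("mircos_partition_error", "train and test roles must be nonempty")
  classes <- sort(unique(labels))
  n_cl <- table(factor(labels, levels = classes))

  # largest-remainder allocation of class 1 across roles; class 2 gets the rest
  q <- counts * as.integer(n_cl[1]) / n
  base <- floor(q)
  rem <- as.integer(n_cl[1]) - sum(base)
  extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
  alloc1 <- base
  alloc1[extra] <- alloc1[extra] + 1
  alloc <- rbind(alloc1, counts - alloc1)
  rownames(alloc) <- classes
  if (any(alloc < 0))
    stop_mircos("mircos_partition_error", "counts not realizable with stratification")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  role <- character(n)
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[order(sample_ids[idx])]     # canonical before shuffling
    idx <- sample(idx)
    r <- rep(names(counts), times = alloc[cl, ])
    role[idx] <- r
  }
  data.frame(sample_id = sample_ids, class = labels, role = role,
             stringsAsFactors = FALSE)
}

#' Render per-sample maps into an image dataset
#'
#' Renders every sample's correlation maps (one image per category) and
#' assigns train/test/external-validation roles with [partition_roles()];
#' the role assignment is drawn once and shared by all categories. A
#' manifest (`sample_id,class,category,role,path`) is written alongside the
#' images.
#'
#' @param maps output of [per_sample_maps()].
#' @param out_dir output directory (created if needed).
#' @param counts role sizes `c(train, test, ev)` summing to the sample count.
#' @param seed seed for the role assignment.
#' @param config a [render_config()].
#' @param categories which categories to render (default all three).
#' @return an `image_dataset`: `manifest` data.frame, `counts`, `config`.
#' @export
build_image_dataset <- function(maps, out_dir,
                                counts = c(train = 84, test = 36, ev = 52),
                                seed = 1, config = render_config(),
                                categories = c("synchronous", "asynchronous",
                                               "integrated")) {
  ids <- vapply(maps, `[[`, character(1), "sample_id")
  labels <- vapply(maps, `[[`, character(1), "class")
  roles <- partition_roles(ids, labels, counts, seed)
  comp <- c(synchronous = "sync", asynchronous = "async",
            integrated = "integrated")
  categories <- match.arg(categories, several.ok = TRUE)
  ext <- if (config$format == "png") ".png" else ".jpg"

  rows <- list()
  for (cat in categories) {
    dir.create(file.path(out_dir, cat), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(maps)) {
      m <- maps[[i]][[comp[[cat]]]]
      if (is.null(m))
        stop_mircos("mircos_mode_error", "category '", cat,
                    "' unavailable for sample ", ids[i])
      p <- file.path(out_dir, cat, paste0(ids[i], ext))
      render_surface(m, p, config)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], class = labels[i], category = cat,
        role = roles$role[i], path = p, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  structure(list(manifest = manifest, counts = counts, config = config),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("image_dataset:", nrow(x$manifest), "images\n")
  print(table(x$manifest$category, x$manifest$role))
  invisible(x)
}

# Decode an image file to an H x W x 3 array in [0, 1].
read_image_array <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    jpeg::readJPEG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
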