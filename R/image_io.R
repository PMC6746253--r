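# Reading and writing pipeline artifacts: images, label maps, probability
# maps, instance maps, trained classifiers, measurement tables.
#
# Images travel as multi-plane 16-bit TIFF plus a JSON sidecar
# ("<path>.json") carrying pixel size, channel names and metadata, since
# baseline TIFF tags have no portable micrometre pixel-size slot. Label and
# instance maps are single-plane integer TIFF (PNG accepted for labels);
# probability maps are stored 32-bit (quantization ~2e-10) to preserve the
# per-pixel normalization. The R TIFF writer has no float sample format, so
# intensities are stored on integer grids; a write/read cycle is exactly
# idempotent, and data originating from 8/16-bit acquisitions round-trips
# bit-exactly.

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-channel image from TIFF
#'
#' Accepts 1-, 2- or 3-plane TIFFs (a 3rd plane is ignored with a warning) or
#' any multi-plane TIFF. Pixel size is taken from the JSON sidecar written by
#' [write_image()] when present, else from the `pixel_size_um` argument, else
#' defaults to 1 micrometre with a warning.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Physical pixel size in micrometres; overridden by a
#'   sidecar value if one exists.
#' @return An [mc_image()].
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop(sprintf("failed to read TIFF '%s': %s",
                                    path, conditionMessage(e))))
  if (length(planes) == 1L && length(dim(planes[[1]])) == 3L) {
    # single directory with multiple samples per pixel (e.g. RGB)
    a <- planes[[1]]
    planes <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
  }
  if (length(planes) == 0L || any(vapply(planes, length, 1L) == 0L))
    stop(sprintf("zero-sized image: %s", path))
  if (length(planes) == 3L) {
    message("read_image: 3-plane TIFF, ignoring 3rd plane")
    planes <- planes[1:2]
  }
  channels <- NULL
  metadata <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$pixel_size_um)) pixel_size_um <- side$pixel_size_um
    if (!is.null(side$channels)) channels <- side$channels
    if (!is.null(side$metadata) && length(side$metadata))
      metadata <- as.list(side$metadata)
  }
  if (is.null(pixel_size_um)) {
    warning("no pixel size in file or argument; defaulting to 1.0 um/px")
    pixel_size_um <- 1.0
  }
  if (length(planes) == 1L)
    message("read_image: single-channel TIFF, channel named 'green'")
  mc_image(planes, channels = channels, pixel_size_um = pixel_size_um,
           metadata = metadata)
}

#' Write a multi-channel image as 16-bit TIFF (+ JSON sidecar)
#'
#' The sidecar stores pixel size, channel names and metadata so that
#' [read_image()] round-trips them. Intensities (expected in `[0, 1]`) are
#' stored on the 16-bit grid; values already on that grid — anything that
#' came from 8/16-bit data or a previous write — round-trip bit-exactly.
#'
#' @param image An [mc_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_mc_image(image)
  px <- lapply(unname(image$pixels), function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(px, path, bits.per.sample = 16)
  meta <- image$metadata
  if (length(meta)) {
    ok <- vapply(meta, function(v) is.atomic(v) && length(v) >= 1, TRUE)
    if (!all(ok)) {
      warning("dropping non-atomic metadata entries on write")
      meta <- meta[ok]
    }
  }
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            channels = names(image$pixels),
                            metadata = meta),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a class label map (TIFF or PNG)
#'
#' Single-plane integer image with values in 0..4; anything else is a format
#' error naming the offending value.
#'
#' @param path TIFF or PNG file.
#' @return Integer label matrix (see [as_label_map()]).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  as_label_map(round(m * 255))
}

#' Write a class label map as 8-bit TIFF or PNG
#' @param labels Label matrix with values in 0..4.
#' @param path Output path; extension `.png` selects PNG, else TIFF.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- as_label_map(labels)
  m <- labels / 255
  if (tolower(tools::file_ext(path)) == "png") png::writePNG(m, path)
  else tiff::writeTIFF(m, path, bits.per.sample = 8)
  invisible(path)
}

#' Read / write a granule instance label image (16-bit TIFF)
#' @param path File path.
#' @return Integer instance matrix.
#' @export
read_instances <- function(path) {
  if (!file.exists(path)) stop(sprintf("instance file not found: %s", path))
  m <- tiff::readTIFF(path)
  as_granule_labels(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
                    relabel = FALSE)
}

#' @rdname read_instances
#' @param labels Integer instance matrix (ids < 65536).
#' @export
write_instances <- function(labels, path) {
  if (max(labels) > 65535) stop("instance ids exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read probability maps as 4-plane 32-bit TIFF
#' @param maps A `probability_maps` object (see [predict_probabilities()]).
#' @param path File path.
#' @export
write_probability_maps <- function(maps, path) {
  stopifnot(inherits(maps, "probability_maps"))
  planes <- lapply(seq_len(dim(maps$maps)[3]), function(k) maps$maps[, , k])
  tiff::writeTIFF(planes, path, bits.per.sample = 32)
  jsonlite::write_json(list(class_order = maps$class_order,
                            source_image_id = maps$source_image_id),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_probability_maps
#' @export
read_probability_maps <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  planes <- tiff::readTIFF(path, all = TRUE)
  class_order <- CLASS_ORDER
  source_id <- NA_character_
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    class_order <- side$class_order %||% class_order
    source_id <- side$source_image_id %||% source_id
  }
  a <- array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)),
             dimnames = list(NULL, NULL, class_order))
  new_probability_maps(a, class_order, source_id)
}

CLASSIFIER_BUNDLE_VERSION <- 1L

#' Save / load a trained classifier bundle
#'
#' The bundle embeds the fitted forest, its [feature_config()], the
#' [classifier_config()], the class order and the package version, so that
#' prediction never needs external configuration. Loading a bundle whose
#' format version differs from the library's is an explicit error.
#'
#' @param model A `trained_classifier` from [train_classifier()].
#' @param path Output file (single-file RDS bundle).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  bundle <- list(format_version = CLASSIFIER_BUNDLE_VERSION,
                 package_version = as.character(utils::packageVersion("starchseg")),
                 model = model)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_classifier
#' @return `load_classifier()` returns the `trained_classifier`.
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop(sprintf("classifier file not found: %s", path))
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, CLASSIFIER_BUNDLE_VERSION))
    stop(sprintf(
      "classifier bundle format %s does not match library format %s",
      bundle$format_version, CLASSIFIER_BUNDLE_VERSION))
  bundle$model
}

#' Write granule measurements (and a per-image summary) to CSV
#'
#' One row per granule with columns `image_id, granule_id, area_um2,
#' perimeter_um, major_um, minor_um, equiv_diameter_um, centroid_x_px,
#' centroid_y_px`. A companion file `<path minus extension>_summary.csv`
#' holds per-image mean and standard error (sd/sqrt(n); 0 when n = 1) for
#' each measured column. An empty table yields a header-only CSV.
#'
#' @param table A `granule_table` from [measure_granules()], or a list of
#'   them (multiple images).
#' @param path Output CSV path.
#' @return Named list with the two file paths, invisibly.
#' @export
write_measurements <- function(table, path) {
  tables <- if (inherits(table, "granule_table")) list(table) else table
  stopifnot(all(vapply(tables, inherits, TRUE, "granule_table")))
  rows <- lapply(tables, function(tb) {
    df <- tb$measurements
    if (nrow(df) == 0) return(NULL)
    cbind(data.frame(image_id = tb$image_id, stringsAsFactors = FALSE), df)
  })
  cols <- c("image_id", "granule_id", "area_um2", "perimeter_um", "major_um",
            "minor_um", "equiv_diameter_um", "centroid_x_px", "centroid_y_px")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  out <- out[, cols]
  write.csv(out, path, row.names = FALSE)

  sm <- do.call(rbind, lapply(tables, function(tb) {
    s <- summarize_granules(tb)$stats
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(image_id = tb$image_id, stringsAsFactors = FALSE), s)
  }))
  if (is.null(sm))
    sm <- data.frame(image_id = character(0), parameter = character(0),
                     mean = numeric(0), standard_error = numeric(0),
                     n = integer(0))
  spath <- paste0(tools::file_path_sans_ext(path), "_summary.csv")
  write.csv(sm, spath, row.names = FALSE)
  invisible(list(measurements = path, summary = spath))
}
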