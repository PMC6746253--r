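# Domain containers. Kept as light S3 lists / plain matrices: images are
# named lists of numeric matrices, label maps and instance maps are integer
# matrices, following the row-major, 0-based pixel convention documented in
# the package vignette (centroid x = column, y = row).

#' Class codes used in pixel label maps
#'
#' 0 = unlabeled, 1 = starch, 2 = plastid, 3 = membrane/cytosol,
#' 4 = background. Code 0 supports sparse (partial) manual labeling; only
#' codes 1-4 are classes the classifier learns.
#'
#' @format Named integer vector.
#' @export
CLASS_CODES <- c(unlabeled = 0L, starch = 1L, plastid = 2L,
                 membrane = 3L, background = 4L)

#' Fixed class order of the classifier and its probability maps
#' @format Character vector of length 4.
#' @export
CLASS_ORDER <- c("starch", "plastid", "membrane", "background")

#' Create a multi-channel image
#'
#' The pipeline's raw input: a 2D pixel grid per channel plus the physical
#' pixel size. All channels must share the same height and width.
#'
#' @param pixels A numeric matrix (single channel) or list of numeric
#'   matrices, one per channel.
#' @param channels Channel names; defaults to `c("green", "red", ...)` for the
#'   first channels (green = carotenoid, red = chlorophyll autofluorescence).
#' @param pixel_size_um Physical edge length of one (square) pixel in
#'   micrometres; must be positive.
#' @param metadata Free-form named list (e.g. excitation/emission notes).
#' @return An object of class `mc_image`: list with elements `pixels`
#'   (named list of matrices), `pixel_size_um`, `metadata`.
#' @export
mc_image <- function(pixels, channels = NULL, pixel_size_um = 1,
                     metadata = list()) {
  if (is.matrix(pixels)) pixels <- list(pixels)
  stopifnot(length(pixels) >= 1L)
  dims <- vapply(pixels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share identical height/width")
  if (any(dims == 0L)) stop("zero-sized image")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (is.null(channels)) {
    default_names <- c("green", "red")
    channels <- if (length(pixels) <= 2L) default_names[seq_along(pixels)]
                else c(default_names, paste0("ch", 3:length(pixels)))
  }
  stopifnot(length(channels) == length(pixels))
  pixels <- lapply(pixels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  names(pixels) <- channels
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 metadata = metadata),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat(sprintf("<mc_image> %d x %d px, %d channel(s) [%s], pixel size %g um\n",
              d[1], d[2], length(x$pixels),
              paste(names(x$pixels), collapse = ", "), x$pixel_size_um))
  invisible(x)
}

#' @export
dim.mc_image <- function(x) dim(x$pixels[[1]])

n_channels <- function(image) length(image$pixels)

assert_mc_image <- function(image) {
  if (!inherits(image, "mc_image")) stop("expected an mc_image object")
  invisible(image)
}

#' Validate a class label map
#'
#' A label map is an integer matrix with values in `CLASS_CODES`
#' (0 = unlabeled .. 4 = background). The shape must match its parent image
#' where one exists.
#'
#' @param labels Integer matrix.
#' @param image Optional `mc_image` the labels annotate (shape check).
#' @return The validated integer matrix (invisibly usable as a LabelMap).
#' @export
as_label_map <- function(labels, image = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  v <- unique(as.vector(labels))
  bad <- setdiff(v, CLASS_CODES)
  if (length(bad) > 0)
    stop(sprintf("label map contains value(s) outside {0..4}: %s",
                 paste(sort(bad), collapse = ", ")))
  if (!is.null(image)) {
    assert_mc_image(image)
    if (!all(dim(labels) == dim(image)))
      stop("label map shape does not match image shape")
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Validate a granule instance label image
#'
#' Non-negative integer matrix: 0 = not-granule, k >= 1 = k-th granule
#' instance. Instance ids are made contiguous 1..N (row-major scan order).
#'
#' @param labels Integer matrix of instance ids.
#' @param relabel Renumber ids to a contiguous 1..N range (default TRUE).
#' @return Integer matrix with contiguous instance ids.
#' @export
as_granule_labels <- function(labels, relabel = TRUE) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("instance labels must be non-negative integers")
  if (relabel) labels <- relabel_rowmajor(labels) else
    storage.mode(labels) <- "integer"
  labels
}
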