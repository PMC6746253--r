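# Contrast enhancement before feature extraction: median filtering followed
# by contrast-limited adaptive histogram equalization (CLAHE), applied
# independently per channel. Defaults follow the standard confocal
# post-processing recipe for negative-contrast starch imaging:
# 3x3 median, CLAHE with block size 20 px, 50 histogram bins, max slope 2.5.

#' Enhancement parameters
#'
#' @param median_radius Median window radius in pixels (window side
#'   `2*radius+1`); radius 0 disables the median step. Default 1 (3x3),
#'   the smallest noise-suppressing window.
#' @param clahe_block_size CLAHE tile side in pixels. Default 20.
#' @param clahe_bins Number of histogram bins. Default 50.
#' @param clahe_max_slope Contrast-limiting maximum slope of the cumulative
#'   histogram mapping (>= 1; 1 leaves the image nearly unchanged).
#'   Default 2.5.
#' @return List of class `enhance_params`.
#' @export
enhance_params <- function(median_radius = 1, clahe_block_size = 20,
                           clahe_bins = 50, clahe_max_slope = 2.5) {
  stopifnot(median_radius >= 0, clahe_block_size >= 2, clahe_bins >= 2,
            clahe_max_slope >= 1)
  structure(list(median_radius = as.integer(median_radius),
                 clahe_block_size = as.integer(clahe_block_size),
                 clahe_bins = as.integer(clahe_bins),
                 clahe_max_slope = clahe_max_slope),
            class = "enhance_params")
}

#' Median filter a single channel
#'
#' Each output pixel is the median of its `(2*radius+1)^2` neighborhood with
#' nearest-pixel (replicate) edge handling; radius 0 is the identity.
#'
#' @param channel Numeric matrix.
#' @param radius Non-negative integer radius.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(channel, radius = 1) {
  stopifnot(is.matrix(channel), radius >= 0)
  storage.mode(channel) <- "double"
  cpp_median_filter(channel, as.integer(radius))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The channel is min-max normalized to `[0, 1]`, then equalized on tiles of
#' side `clahe_block_size` with `clahe_bins` histogram bins and the clip
#' limit set by `clahe_max_slope` (the maximum slope of the tile's cumulative
#' histogram mapping, i.e. the ImageJ-style parameterization). A block size
#' larger than the image falls back to a single global tile with a message.
#'
#' @param channel Numeric matrix.
#' @param params An [enhance_params()].
#' @return Equalized matrix in `[0, 1]`.
#' @export
clahe <- function(channel, params = enhance_params()) {
  stopifnot(is.matrix(channel), inherits(params, "enhance_params"))
  x <- normalize01(channel)
  if (max(x) - min(x) < .Machine$double.eps) return(x)  # nothing to equalize
  h <- nrow(x); w <- ncol(x)
  bs <- params$clahe_block_size
  if (bs > h || bs > w) {
    message("clahe: block size exceeds image; using a single global tile")
    return(clahe_global(x, params$clahe_bins, params$clahe_max_slope))
  } else {
    # number of tiles along each matrix dimension (EBImage needs >= 2x2)
    ny <- max(2L, as.integer(round(h / bs)))
    nx <- max(2L, as.integer(round(w / bs)))
  }
  # EBImage's CLAHE needs dimensions divisible by the tile counts: replicate-
  # pad up to the next multiple, equalize, crop back.
  ph <- as.integer(ceiling(h / ny) * ny)
  pw <- as.integer(ceiling(w / nx) * nx)
  xp <- x[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)),
          drop = FALSE]
  # EBImage images are indexed (x, y): transpose so tiles line up with nx/ny
  r <- EBImage::clahe(t(xp), nx = nx, ny = ny, bins = params$clahe_bins,
                      limit = params$clahe_max_slope, keep.range = FALSE)
  if (methods::is(r, "Image")) r <- EBImage::imageData(r)
  out <- t(r)[seq_len(h), seq_len(w), drop = FALSE]
  pmin(pmax(out, 0), 1)
}

# Single-tile contrast-limited equalization: histogram clipped at
# max_slope/bins with the excess redistributed uniformly, then the clipped
# CDF is used as the intensity mapping.
clahe_global <- function(x, bins, max_slope) {
  idx <- pmin(floor(x * bins) + 1L, bins)
  h <- tabulate(idx, bins) / length(x)
  cap <- max_slope / bins
  clipped <- pmin(h, cap)
  h2 <- clipped + (1 - sum(clipped)) / bins
  cdf <- cumsum(h2)
  out <- matrix(cdf[idx], nrow(x), ncol(x))
  pmin(pmax(out, 0), 1)
}

#' Enhance all channels of an image (median filter + CLAHE)
#'
#' Applies [median_filter()] then [clahe()] independently to every channel;
#' the parameters used are recorded in the image metadata. Output intensities
#' are in `[0, 1]`. Deterministic: identical input and parameters give
#' identical output.
#'
#' @param image An [mc_image()].
#' @param params An [enhance_params()].
#' @return Enhanced [mc_image()].
#' @export
enhance <- function(image, params = enhance_params()) {
  assert_mc_image(image)
  px <- lapply(image$pixels, function(ch)
    clahe(median_filter(ch, params$median_radius), params))
  meta <- image$metadata
  meta$enhance_params <- unclass(params)
  mc_image(px, channels = names(image$pixels),
           pixel_size_um = image$pixel_size_um, metadata = meta)
}
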