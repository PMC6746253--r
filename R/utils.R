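# Internal helpers shared across modules.

# Replicate-pad a matrix by (pr, pc) on each side.
pad_replicate <- function(x, pr, pc = pr) {
  h <- nrow(x); w <- ncol(x)
  x[pmin(pmax(seq_len(h + 2 * pr) - pr, 1L), h),
    pmin(pmax(seq_len(w + 2 * pc) - pc, 1L), w), drop = FALSE]
}

# 2D convolution with replicate (nearest-pixel) border handling; kernels
# larger than the image are supported by pre-padding.
conv2 <- function(x, kern) {
  pr <- max(0L, as.integer(ceiling((nrow(kern) - nrow(x)) / 2)) + 1L)
  pc <- max(0L, as.integer(ceiling((ncol(kern) - ncol(x)) / 2)) + 1L)
  if (pr > 1L || pc > 1L) {
    xp <- pad_replicate(x, pr, pc)
    r <- EBImage::filter2(xp, kern, boundary = "replicate")
    if (methods::is(r, "Image")) r <- EBImage::imageData(r)
    return(r[pr + seq_len(nrow(x)), pc + seq_len(ncol(x)), drop = FALSE])
  }
  r <- EBImage::filter2(x, kern, boundary = "replicate")
  if (methods::is(r, "Image")) r <- EBImage::imageData(r)
  r
}

# Gaussian smoothing, replicate border, robust to small images.
gsmooth <- function(x, sigma) {
  radius <- 2 * ceiling(3 * sigma) + 1
  if (radius > min(dim(x))) {
    kern <- EBImage::makeBrush(radius, shape = "Gaussian", sigma = sigma)
    return(conv2(x, kern))
  }
  r <- EBImage::gblur(x, sigma = sigma, boundary = "replicate")
  if (methods::is(r, "Image")) r <- EBImage::imageData(r)
  r
}

# Shift a matrix by (dr, dc); out[i, j] = x[i - dr, j - dc] with replicate
# border, i.e. positive dr moves content towards higher row indices.
shift_mat <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  x[ri, ci, drop = FALSE]
}

# Normalized disk kernel of the given radius (pixels).
disk_kernel <- function(radius) {
  r <- max(1L, as.integer(round(radius)))
  d <- 2L * r + 1L
  ix <- matrix(rep(-r:r, d), d, d)
  k <- (ix^2 + t(ix)^2) <= r^2 + 1e-9
  k <- k * 1.0
  k / sum(k)
}

# Min-max scale a matrix to [0, 1]; constant input is clamped, not rescaled.
normalize01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps) return(pmin(pmax(x, 0), 1))
  (x - lo) / (hi - lo)
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Relabel a non-negative integer instance image so that surviving instances
# are numbered 1..N in top-left-first row-major scan order (rows scanned
# left-to-right, top-to-bottom).
relabel_rowmajor <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  w <- ncol(labels)
  nz <- which(labels > 0)
  i <- (nz - 1L) %% nrow(labels) + 1L
  j <- (nz - 1L) %/% nrow(labels) + 1L
  pos <- (i - 1L) * w + j  # row-major linear position
  first <- tapply(pos, labels[nz], min)
  ord <- as.integer(names(first))[order(first)]
  map <- integer(max(ids))
  map[ord] <- seq_along(ord)
  out <- labels
  out[nz] <- map[labels[nz]]
  storage.mode(out) <- "integer"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
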