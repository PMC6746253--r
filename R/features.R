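# Multi-scale per-pixel filter bank for trainable pixel classification.
# Fourteen filter families over a scale ladder, computed independently per
# channel; the shipped default configuration yields 151 feature planes per
# channel (302 on a two-channel image). Per-family plane counts, with
# S = length(sigmas):
#   original 1; gaussian_blur S; sobel S; hessian 6*S (module, trace,
#   determinant, both eigenvalues, orientation); difference_of_gaussians
#   S*(S-1)/2; membrane_projections 6 (sum/mean/sd/median/max/min across
#   rotations); mean S; variance S; anisotropic_diffusion one per iteration
#   count; bilateral one per spatial-sigma x range-sigma pair; lipschitz one
#   per slope; kuwahara one per window size; gabor orientations x
#   frequencies; entropy S; neighbors 8*S (unit offsets scaled by sigma).

FEATURE_FAMILIES <- c("gaussian_blur", "sobel", "hessian",
                      "difference_of_gaussians", "membrane_projections",
                      "variance", "mean", "anisotropic_diffusion",
                      "bilateral", "lipschitz", "kuwahara", "gabor",
                      "entropy", "neighbors")

SCALE_FAMILIES <- c("gaussian_blur", "sobel", "hessian",
                    "difference_of_gaussians", "variance", "mean",
                    "entropy", "neighbors")

#' Feature bank configuration
#'
#' @param families Subset of the 14 filter families (default all).
#' @param sigmas Strictly increasing positive scale ladder in pixels.
#'   Default `c(1, 2, 4, 8, 16)`, the standard power-of-two ladder.
#' @param membrane_kernel_size Side of the rotated line kernel (px).
#' @param membrane_n_rotations Number of kernel rotations over 180 degrees.
#' @param gabor_orientations Number of Gabor orientations over 180 degrees.
#' @param gabor_frequencies Gabor spatial frequencies (cycles/px).
#' @param neighbor_radius Chebyshev radius of the neighbor offsets (default 1
#'   = the 8 surrounding pixels; offsets are scaled by each sigma).
#' @param diffusion_iterations Snapshot iteration counts of the
#'   Perona-Malik anisotropic diffusion.
#' @param bilateral_spatial Spatial Gaussian sds (px) of the bilateral filter.
#' @param bilateral_range Range Gaussian sds (intensity units).
#' @param lipschitz_slopes Cone slopes (intensity per px) of the lower
#'   envelope (Lipschitz cover) transform.
#' @param kuwahara_sizes Odd window sizes of the quadrant-mean filter.
#' @param entropy_bins Histogram bins of the local-entropy filter.
#' @param include_original Include the unfiltered intensity plane.
#' @param channels_used Channel names fed to the bank (`NULL` = all).
#' @return List of class `feature_config`.
#' @export
feature_config <- function(families = FEATURE_FAMILIES,
                           sigmas = c(1, 2, 4, 8, 16),
                           membrane_kernel_size = 19,
                           membrane_n_rotations = 30,
                           gabor_orientations = 8,
                           gabor_frequencies = c(0.1, 0.2, 0.4),
                           neighbor_radius = 1,
                           diffusion_iterations = c(1, 5, 10, 20),
                           bilateral_spatial = c(3, 5),
                           bilateral_range = c(0.1, 0.25),
                           lipschitz_slopes = c(0.005, 0.01, 0.02, 0.04),
                           kuwahara_sizes = c(9, 13, 17),
                           entropy_bins = 10,
                           include_original = TRUE,
                           channels_used = NULL) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  if (length(families) == 0) stop("families must be non-empty")
  if (any(families %in% SCALE_FAMILIES)) {
    if (length(sigmas) == 0)
      stop("scale-dependent families configured but sigmas is empty")
    if (any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE))
      stop("sigmas must be strictly increasing and positive")
  }
  stopifnot(membrane_kernel_size %% 2 == 1, membrane_n_rotations >= 1,
            gabor_orientations >= 1, length(gabor_frequencies) >= 1,
            neighbor_radius >= 1, all(kuwahara_sizes %% 2 == 1),
            entropy_bins >= 2)
  structure(list(families = families, sigmas = sigmas,
                 membrane_kernel_size = as.integer(membrane_kernel_size),
                 membrane_n_rotations = as.integer(membrane_n_rotations),
                 gabor_orientations = as.integer(gabor_orientations),
                 gabor_frequencies = gabor_frequencies,
                 neighbor_radius = as.integer(neighbor_radius),
                 diffusion_iterations = as.integer(diffusion_iterations),
                 bilateral_spatial = bilateral_spatial,
                 bilateral_range = bilateral_range,
                 lipschitz_slopes = lipschitz_slopes,
                 kuwahara_sizes = as.integer(kuwahara_sizes),
                 entropy_bins = as.integer(entropy_bins),
                 include_original = isTRUE(include_original),
                 channels_used = channels_used),
            class = "feature_config")
}

fmt_num <- function(x)
  vapply(x, function(v) gsub("[^0-9a-zA-Z]", "p", format(v, trim = TRUE)), "")

neighbor_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[!(g$dr == 0 & g$dc == 0), , drop = FALSE]
}

# Feature names for one channel, in deterministic order.
channel_feature_names <- function(config) {
  s <- config$sigmas
  nm <- character(0)
  if (config$include_original) nm <- c(nm, "original")
  for (fam in config$families) {
    nm <- c(nm, switch(fam,
      gaussian_blur = sprintf("gaussian_s%s", fmt_num(s)),
      sobel = sprintf("sobel_s%s", fmt_num(s)),
      hessian = as.vector(outer(
        c("module", "trace", "det", "eig1", "eig2", "orient"), fmt_num(s),
        function(a, b) sprintf("hessian_%s_s%s", a, b))),
      difference_of_gaussians = {
        p <- which(upper.tri(diag(length(s))), arr.ind = TRUE)
        p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
        sprintf("dog_s%s_s%s", fmt_num(s[p[, 1]]), fmt_num(s[p[, 2]]))
      },
      membrane_projections = sprintf(
        "membrane_%s_k%d", c("sum", "mean", "sd", "median", "max", "min"),
        config$membrane_kernel_size),
      variance = sprintf("variance_s%s", fmt_num(s)),
      mean = sprintf("mean_s%s", fmt_num(s)),
      anisotropic_diffusion = sprintf("aniso_i%d",
                                      config$diffusion_iterations),
      bilateral = as.vector(t(outer(
        config$bilateral_spatial, config$bilateral_range,
        function(a, b) sprintf("bilateral_ss%s_sr%s",
                               fmt_num(a), fmt_num(b))))),
      lipschitz = sprintf("lipschitz_sl%s", fmt_num(config$lipschitz_slopes)),
      kuwahara = sprintf("kuwahara_k%d", config$kuwahara_sizes),
      gabor = {
        o <- seq_len(config$gabor_orientations) - 1L
        as.vector(t(outer(config$gabor_frequencies, o,
                          function(f, k) sprintf("gabor_f%s_o%d",
                                                 fmt_num(f), k))))
      },
      entropy = sprintf("entropy_s%s", fmt_num(s)),
      neighbors = {
        off <- neighbor_offsets(config$neighbor_radius)
        unlist(lapply(s, function(sg)
          sprintf("neighbor_%s_%s_s%s",
                  fmt_num(off$dr), fmt_num(off$dc), fmt_num(sg))))
      }))
  }
  nm
}

#' Enumerate feature names
#'
#' Deterministic ordered names of every feature plane the configuration
#' produces on an image with `n_channels` channels. Channel prefixes are
#' positional (`ch1_`, `ch2_`, ...) so that a trained model applies to any
#' image with the right channel count. The shipped default configuration on
#' two channels yields more than 300 features.
#'
#' @param config A [feature_config()].
#' @param n_channels Number of image channels.
#' @return Character vector of unique feature names.
#' @export
list_feature_names <- function(config = feature_config(), n_channels = 2) {
  stopifnot(inherits(config, "feature_config"), n_channels >= 1)
  base <- channel_feature_names(config)
  unlist(lapply(seq_len(n_channels), function(k) paste0("ch", k, "_", base)))
}

# ---- per-family computations (one channel) ---------------------------------

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 8  # d/dcol
deriv_row <- function(x) (shift_mat(x, -1, 0) - shift_mat(x, 1, 0)) / 2
deriv_col <- function(x) (shift_mat(x, 0, -1) - shift_mat(x, 0, 1)) / 2

hessian_planes <- function(g) {
  gxx <- shift_mat(g, 0, -1) - 2 * g + shift_mat(g, 0, 1)   # d2/dcol2
  gyy <- shift_mat(g, -1, 0) - 2 * g + shift_mat(g, 1, 0)   # d2/drow2
  gxy <- deriv_row(deriv_col(g))
  tr <- gxx + gyy
  disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
  list(module = sqrt(gxx^2 + 2 * gxy^2 + gyy^2),
       trace = tr,
       det = gxx * gyy - gxy^2,
       eig1 = (tr + disc) / 2,
       eig2 = (tr - disc) / 2,
       orient = 0.5 * atan2(2 * gxy, gyy - gxx))
}

membrane_kernels <- function(size, n_rot) {
  half <- (size - 1) / 2
  co <- matrix(rep(-half:half, size), size, size)  # column offset
  ro <- t(co)                                      # row offset
  lapply(seq_len(n_rot) - 1L, function(i) {
    th <- pi * i / n_rot
    v <- c(cos(th), sin(th))             # line direction (row, col)
    dperp <- abs(ro * (-v[2]) + co * v[1])
    dpar <- abs(ro * v[1] + co * v[2])
    k <- (dperp <= 0.5) & (dpar <= half + 1e-9)
    k <- k * 1.0
    k / sum(k)
  })
}

gabor_kernel <- function(freq, theta, phase) {
  sigma <- 0.56 / freq
  half <- ceiling(2.5 * sigma)
  co <- matrix(rep(-half:half, 2 * half + 1), 2 * half + 1)
  ro <- t(co)
  xr <- ro * cos(theta) + co * sin(theta)
  yr <- -ro * sin(theta) + co * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  env * cos(2 * pi * freq * xr + phase)
}

perona_malik <- function(x, snapshots, kappa = 0.1, lambda = 0.15) {
  out <- vector("list", length(snapshots))
  for (it in seq_len(max(snapshots))) {
    dn <- shift_mat(x, 1, 0) - x
    ds <- shift_mat(x, -1, 0) - x
    de <- shift_mat(x, 0, 1) - x
    dw <- shift_mat(x, 0, -1) - x
    x <- x + lambda * (exp(-(dn / kappa)^2) * dn + exp(-(ds / kappa)^2) * ds +
                       exp(-(de / kappa)^2) * de + exp(-(dw / kappa)^2) * dw)
    hit <- which(snapshots == it)
    if (length(hit)) out[hit] <- list(x)
  }
  out
}

# Exact L1-cone lower envelope (min-plus erosion with an L1 cone of the given
# slope): 1D envelopes along rows then columns.
lipschitz_envelope <- function(x, slope) {
  h <- nrow(x); w <- ncol(x)
  e <- x
  if (h > 1) {
    for (i in 2:h) e[i, ] <- pmin(e[i, ], e[i - 1, ] + slope)
    for (i in (h - 1):1) e[i, ] <- pmin(e[i, ], e[i + 1, ] + slope)
  }
  if (w > 1) {
    for (j in 2:w) e[, j] <- pmin(e[, j], e[, j - 1] + slope)
    for (j in (w - 1):1) e[, j] <- pmin(e[, j], e[, j + 1] + slope)
  }
  e
}

kuwahara_filter <- function(x, size) {
  q <- (size + 1L) %/% 2L          # quadrant side (odd by construction)
  d <- (q - 1L) %/% 2L             # shift from window center to quadrant center
  box <- matrix(1 / q^2, q, q)
  m1 <- conv2(x, box)
  m2 <- conv2(x * x, box)
  best_m <- NULL; best_v <- NULL
  for (sr in c(-d, d)) for (sc in c(-d, d)) {
    qm <- shift_mat(m1, sr, sc)
    qv <- pmax(shift_mat(m2, sr, sc) - qm^2, 0)
    if (is.null(best_v)) { best_m <- qm; best_v <- qv }
    else {
      take <- qv < best_v
      best_m[take] <- qm[take]
      best_v[take] <- qv[take]
    }
  }
  best_m
}

local_entropy <- function(x, radius, bins) {
  xn <- normalize01(x)
  k <- disk_kernel(radius)
  idx <- pmin(floor(xn * bins) + 1L, bins)
  ent <- matrix(0, nrow(x), ncol(x))
  for (b in seq_len(bins)) {
    p <- conv2((idx == b) * 1.0, k)
    p <- pmax(p, 0)
    nz <- p > 1e-12
    ent[nz] <- ent[nz] - p[nz] * log(p[nz])
  }
  ent
}

compute_channel_features <- function(x, config) {
  s <- config$sigmas
  g <- lapply(s, function(sg) gsmooth(x, sg))
  names(g) <- as.character(s)
  planes <- list()
  add <- function(p, nm) {
    names(p) <- nm
    planes[[length(planes) + 1]] <<- p
  }
  if (config$include_original) add(list(x), "original")
  for (fam in config$families) {
    switch(fam,
      gaussian_blur = add(g, sprintf("gaussian_s%s", fmt_num(s))),
      sobel = add(lapply(g, function(gs) {
        gx <- conv2(gs, sobel_x); gy <- conv2(gs, t(sobel_x))
        sqrt(gx^2 + gy^2)
      }), sprintf("sobel_s%s", fmt_num(s))),
      hessian = {
        for (i in seq_along(s)) {
          hp <- hessian_planes(g[[i]])
          add(hp, sprintf("hessian_%s_s%s", names(hp), fmt_num(s[i])))
        }
      },
      difference_of_gaussians = {
        p <- which(upper.tri(diag(length(s))), arr.ind = TRUE)
        p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
        add(lapply(seq_len(nrow(p)), function(r) g[[p[r, 1]]] - g[[p[r, 2]]]),
            sprintf("dog_s%s_s%s", fmt_num(s[p[, 1]]), fmt_num(s[p[, 2]])))
      },
      membrane_projections = {
        ks <- membrane_kernels(config$membrane_kernel_size,
                               config$membrane_n_rotations)
        resp <- vapply(ks, function(k) conv2(x, k),
                       matrix(0, nrow(x), ncol(x)))
        rm2 <- matrix(resp, nrow(x) * ncol(x), length(ks))
        mu <- rowMeans(rm2)
        sdev <- sqrt(pmax(rowMeans(rm2^2) - mu^2, 0))
        mx <- rm2[, 1]; mn <- rm2[, 1]
        for (cc in seq_len(ncol(rm2))[-1]) {
          mx <- pmax(mx, rm2[, cc]); mn <- pmin(mn, rm2[, cc])
        }
        wrap <- function(v) matrix(v, nrow(x), ncol(x))
        add(list(wrap(mu * length(ks)), wrap(mu), wrap(sdev),
                 wrap(cpp_row_medians(rm2)), wrap(mx), wrap(mn)),
            sprintf("membrane_%s_k%d",
                    c("sum", "mean", "sd", "median", "max", "min"),
                    config$membrane_kernel_size))
      },
      variance = add(lapply(s, function(sg) {
        k <- disk_kernel(sg)
        pmax(conv2(x * x, k) - conv2(x, k)^2, 0)
      }), sprintf("variance_s%s", fmt_num(s))),
      mean = add(lapply(s, function(sg) conv2(x, disk_kernel(sg))),
                 sprintf("mean_s%s", fmt_num(s))),
      anisotropic_diffusion = add(
        perona_malik(x, snapshots = config$diffusion_iterations),
        sprintf("aniso_i%d", config$diffusion_iterations)),
      bilateral = {
        for (ss in config$bilateral_spatial) for (sr in config$bilateral_range)
          add(list(cpp_bilateral(x, as.integer(2 * ss), ss, sr)),
              sprintf("bilateral_ss%s_sr%s", fmt_num(ss), fmt_num(sr)))
      },
      lipschitz = add(lapply(config$lipschitz_slopes,
                             function(sl) lipschitz_envelope(x, sl)),
                      sprintf("lipschitz_sl%s", fmt_num(config$lipschitz_slopes))),
      kuwahara = add(lapply(config$kuwahara_sizes,
                            function(k) kuwahara_filter(x, k)),
                     sprintf("kuwahara_k%d", config$kuwahara_sizes)),
      gabor = {
        for (f in config$gabor_frequencies) {
          for (o in seq_len(config$gabor_orientations) - 1L) {
            th <- pi * o / config$gabor_orientations
            re <- conv2(x, gabor_kernel(f, th, 0))
            im <- conv2(x, gabor_kernel(f, th, pi / 2))
            add(list(sqrt(re^2 + im^2)), sprintf("gabor_f%s_o%d", fmt_num(f), o))
          }
        }
      },
      entropy = add(lapply(s, function(sg)
        local_entropy(x, sg, config$entropy_bins)),
        sprintf("entropy_s%s", fmt_num(s))),
      neighbors = {
        off <- neighbor_offsets(config$neighbor_radius)
        for (sg in s) {
          d <- as.integer(round(sg))
          add(lapply(seq_len(nrow(off)), function(r)
            shift_mat(x, off$dr[r] * d, off$dc[r] * d)),
            sprintf("neighbor_%s_%s_s%s",
                    fmt_num(off$dr), fmt_num(off$dc), fmt_num(sg)))
        }
      })
  }
  planes <- unlist(planes, recursive = FALSE)
  planes
}

#' Compute the per-pixel feature stack
#'
#' One finite feature plane per name in [list_feature_names()], computed
#' independently per channel with replicate border handling. The result is
#' deterministic.
#'
#' @param image An [mc_image()] (typically after [enhance()]).
#' @param config A [feature_config()].
#' @return List of class `feature_stack`: `values` (height x width x
#'   n_features array), `names`, `config`.
#' @export
compute_feature_stack <- function(image, config = feature_config()) {
  assert_mc_image(image)
  chans <- config$channels_used %||% names(image$pixels)
  missing <- setdiff(chans, names(image$pixels))
  if (length(missing))
    stop(sprintf("image lacks configured channel(s): %s",
                 paste(missing, collapse = ", ")))
  nm_expected <- list_feature_names(config, length(chans))
  h <- nrow(image$pixels[[1]]); w <- ncol(image$pixels[[1]])
  values <- array(0, dim = c(h, w, length(nm_expected)))
  k <- 0L
  got <- character(0)
  for (ci in seq_along(chans)) {
    pl <- compute_channel_features(image$pixels[[chans[ci]]], config)
    for (p in pl) values[, , (k <- k + 1L)] <- p
    got <- c(got, paste0("ch", ci, "_", names(pl)))
  }
  stopifnot(identical(got, nm_expected))
  if (!all(is.finite(values))) stop("non-finite values in feature stack")
  dimnames(values) <- list(NULL, NULL, nm_expected)
  structure(list(values = values, names = nm_expected, config = config),
            class = "feature_stack")
}

# Flatten a feature stack to a pixels x features matrix (column-major pixel
# order, matching R's matrix linearization).
feature_matrix <- function(stack) {
  d <- dim(stack$values)
  m <- stack$values
  dim(m) <- c(d[1] * d[2], d[3])
  colnames(m) <- stack$names
  m
}
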