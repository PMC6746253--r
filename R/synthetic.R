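# Synthetic two-channel leaf scenes with instance-level ground truth.
#
# Geometry is sampled in micrometres and rasterized at render time through
# the pixel size, so phenotypes are resolution-independent. Each scene is a
# field of bright, textured elliptical plastids containing dark granule
# ellipses, with thin bright membrane lines (Voronoi cell borders) on a dark
# background. Both channels share the geometry but get independent stroma
# textures and noise, echoing the different carotenoid/chlorophyll signals.

#' Phenotype presets
#'
#' `"wildtype"`: 5-7 granules per plastid, granule diameter Gaussian with
#' mean 0.9 um and sd 0.05, truncated to 0.8-1.0 um, nearly round
#' (aspect 1.0-1.3). `"ss4"`: 0-2 granules per plastid, diameter mean 1.8 um
#' sd 0.3 (truncated 1.0-2.8), aspect up to 1.8 — fewer, larger, more
#' irregular granules, the classic starch-synthase-4 mutant phenotype.
#'
#' @param name `"wildtype"` or `"ss4"`.
#' @return List of class `scene_phenotype`.
#' @export
phenotype_preset <- function(name) {
  presets <- list(
    wildtype = scene_phenotype(
      granules_per_plastid = c(5, 7),
      granule_diameter_um = list(mean = 0.9, sd = 0.05, lo = 0.8, hi = 1.0),
      granule_aspect_ratio = c(1.0, 1.3),
      plastid_diameter_um = c(4, 7),
      plastids_per_image = c(4, 6),
      out_of_focus_fraction = 0.1),
    ss4 = scene_phenotype(
      granules_per_plastid = c(0, 2),
      granule_diameter_um = list(mean = 1.8, sd = 0.3, lo = 1.0, hi = 2.8),
      granule_aspect_ratio = c(1.0, 1.8),
      plastid_diameter_um = c(4, 7),
      plastids_per_image = c(4, 6),
      out_of_focus_fraction = 0.1))
  if (!name %in% names(presets))
    stop(sprintf("unknown phenotype '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  presets[[name]]
}

#' Scene phenotype parameters
#'
#' @param granules_per_plastid Integer range (lo, hi).
#' @param granule_diameter_um List `(mean, sd, lo, hi)` of the truncated
#'   Gaussian granule equivalent-diameter distribution, micrometres.
#' @param granule_aspect_ratio Range of granule major/minor axis ratios.
#' @param plastid_diameter_um Range of plastid mean diameters, micrometres.
#' @param plastids_per_image Integer range of plastids per scene.
#' @param out_of_focus_fraction Fraction of granules rendered blurred and
#'   low-contrast, flagged `in_focus = FALSE` in the truth table.
#' @return List of class `scene_phenotype`.
#' @export
scene_phenotype <- function(granules_per_plastid = c(5, 7),
                            granule_diameter_um = list(mean = 0.9, sd = 0.05,
                                                       lo = 0.8, hi = 1.0),
                            granule_aspect_ratio = c(1.0, 1.3),
                            plastid_diameter_um = c(4, 7),
                            plastids_per_image = c(4, 6),
                            out_of_focus_fraction = 0.1) {
  stopifnot(granules_per_plastid[1] >= 0, diff(granules_per_plastid) >= 0,
            granule_diameter_um$lo > 0,
            granule_diameter_um$hi >= granule_diameter_um$lo,
            all(granule_aspect_ratio >= 1), all(plastid_diameter_um > 0),
            plastids_per_image[1] >= 0,
            out_of_focus_fraction >= 0, out_of_focus_fraction < 1)
  structure(list(granules_per_plastid = as.integer(granules_per_plastid),
                 granule_diameter_um = granule_diameter_um,
                 granule_aspect_ratio = granule_aspect_ratio,
                 plastid_diameter_um = plastid_diameter_um,
                 plastids_per_image = as.integer(plastids_per_image),
                 out_of_focus_fraction = out_of_focus_fraction),
            class = "scene_phenotype")
}

#' Rendering parameters
#'
#' @param pixel_size_um Pixel size, micrometres (default 0.1, the Nyquist
#'   sampling of a 1.4-NA objective at ~500 nm).
#' @param image_size_px Square image side in pixels.
#' @param psf_sigma_px Gaussian optical blur sd, pixels.
#' @param texture_contrast Relative amplitude of the smooth stroma texture.
#' @param granule_darkness Granule-to-stroma intensity ratio (< 1: granules
#'   must be darker than the surrounding stroma — the negative-contrast
#'   premise of the method).
#' @param membrane_intensity Membrane line intensity (green channel;
#'   the red channel uses 0.75 x this).
#' @param noise_gaussian_sd Additive read-noise sd.
#' @param noise_shot_scale Scale of the intensity-dependent (Poisson-like)
#'   noise term: sd = `noise_shot_scale * sqrt(intensity)`.
#' @param oof_extra_blur_px Extra blur applied to out-of-focus granules.
#' @param oof_darkness Intensity ratio of out-of-focus granules (closer to
#'   1 than `granule_darkness`: reduced contrast).
#' @return List of class `render_params`.
#' @export
render_params <- function(pixel_size_um = 0.1, image_size_px = 256,
                          psf_sigma_px = 1.2, texture_contrast = 0.12,
                          granule_darkness = 0.15, membrane_intensity = 0.42,
                          noise_gaussian_sd = 0.04, noise_shot_scale = 0.05,
                          oof_extra_blur_px = 3, oof_darkness = 0.55) {
  stopifnot(pixel_size_um > 0, image_size_px >= 16, granule_darkness < 1,
            granule_darkness >= 0, oof_darkness < 1)
  structure(list(pixel_size_um = pixel_size_um,
                 image_size_px = as.integer(image_size_px),
                 psf_sigma_px = psf_sigma_px,
                 texture_contrast = texture_contrast,
                 granule_darkness = granule_darkness,
                 membrane_intensity = membrane_intensity,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_shot_scale = noise_shot_scale,
                 oof_extra_blur_px = oof_extra_blur_px,
                 oof_darkness = oof_darkness),
            class = "render_params")
}

sample_range <- function(rng) if (rng[1] >= rng[2]) rng[1] else
  sample(seq(rng[1], rng[2]), 1)

runif_range <- function(rng) runif(1, rng[1], rng[2])

rtrunc_norm <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    v <- rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

# Rasterize a filled ellipse into a logical h x w matrix. Coordinates in um;
# pixel (i, j) has its center at ((j - 0.5) * psz, (i - 0.5) * psz).
rasterize_ellipse <- function(h, w, psz, cx, cy, a, b, theta) {
  m <- matrix(FALSE, h, w)
  r <- max(a, b)
  rows <- max(1L, floor((cy - r) / psz)):min(h, ceiling((cy + r) / psz + 1))
  cols <- max(1L, floor((cx - r) / psz)):min(w, ceiling((cx + r) / psz + 1))
  if (length(rows) == 0 || length(cols) == 0) return(m)
  xs <- (cols - 0.5) * psz - cx
  ys <- (rows - 0.5) * psz - cy
  X <- matrix(rep(xs, each = length(rows)), length(rows))
  Y <- matrix(rep(ys, length(cols)), length(rows))
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  m[rows, cols] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

#' Generate one synthetic leaf scene
#'
#' Samples non-overlapping plastid ellipses (error after a capped number of
#' rejection attempts), places granule ellipses fully inside their plastid
#' without mutual overlap (a granule that cannot be placed after the attempt
#' cap is dropped), renders both channels (background, bright membrane
#' lines, textured stroma, dark granules, extra blur and reduced contrast
#' for the out-of-focus fraction), applies the optical blur and noise.
#' Dense class labels and instance ground truth are taken before blur and
#' noise. Fully deterministic given the seed.
#'
#' @param phenotype A [scene_phenotype()] or preset name.
#' @param render A [render_params()].
#' @param seed Integer seed.
#' @return Object of class `synthetic_scene`: `image` ([mc_image()]),
#'   `class_labels`, `granule_truth`, `granule_truth_table` (one row per
#'   granule: centre, semi-axes, angle, diameter, `in_focus`, parent
#'   plastid), `phenotype`, `render`, `seed`.
#' @export
generate_scene <- function(phenotype = phenotype_preset("wildtype"),
                           render = render_params(), seed = 1) {
  if (is.character(phenotype)) phenotype <- phenotype_preset(phenotype)
  stopifnot(inherits(phenotype, "scene_phenotype"),
            inherits(render, "render_params"))
  with_seed(seed, {
    psz <- render$pixel_size_um
    npx <- render$image_size_px
    W <- npx * psz
    h <- npx; w <- npx

    # --- membrane: Voronoi cell borders of random seed points -------------
    n_seeds <- max(4L, as.integer(round(W^2 / 110)))
    sx <- runif(n_seeds, 0, W); sy <- runif(n_seeds, 0, W)
    px <- (seq_len(w) - 0.5) * psz
    py <- (seq_len(h) - 0.5) * psz
    PX <- matrix(rep(px, each = h), h)
    PY <- matrix(rep(py, w), h)
    d1 <- matrix(Inf, h, w); d2 <- matrix(Inf, h, w)
    for (k in seq_len(n_seeds)) {
      dk <- sqrt((PX - sx[k])^2 + (PY - sy[k])^2)
      closer <- dk < d1
      d2 <- ifelse(closer, d1, pmin(d2, dk))
      d1 <- pmin(d1, dk)
    }
    membrane <- (d2 - d1) < 0.12

    # --- plastids ---------------------------------------------------------
    n_plastids <- sample_range(phenotype$plastids_per_image)
    margin <- 0.2
    pl <- list()
    for (p in seq_len(n_plastids)) {
      placed <- FALSE
      for (att in 1:500) {
        d <- runif_range(phenotype$plastid_diameter_um)
        ar <- runif(1, 1.0, 1.4)
        sa <- d / 2 * sqrt(ar); sb <- d / 2 / sqrt(ar)
        if (2 * (sa + margin) >= W) next
        cx <- runif(1, sa + margin, W - sa - margin)
        cy <- runif(1, sa + margin, W - sa - margin)
        th <- runif(1, 0, pi)
        ok <- TRUE
        for (q in pl)
          if (sqrt((cx - q$cx)^2 + (cy - q$cy)^2) <= sa + q$sa + 0.2) {
            ok <- FALSE; break
          }
        if (ok) {
          pl[[p]] <- list(cx = cx, cy = cy, sa = sa, sb = sb, theta = th)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all plastids; use fewer or smaller plastids")
    }

    # --- granules ---------------------------------------------------------
    gd <- phenotype$granule_diameter_um
    granules <- list()
    for (p in seq_along(pl)) {
      q <- pl[[p]]
      k <- sample_range(phenotype$granules_per_plastid)
      for (gi in seq_len(k)) {
        for (att in 1:200) {
          d <- rtrunc_norm(gd$mean, gd$sd, gd$lo, gd$hi)
          gar <- runif_range(phenotype$granule_aspect_ratio)
          ga <- d / 2 * sqrt(gar); gb <- d / 2 / sqrt(gar)
          avail_a <- q$sa - ga - 0.2
          avail_b <- q$sb - ga - 0.2
          if (avail_b <= 0) break  # plastid too small for this granule
          phi <- runif(1, 0, 2 * pi); tt <- sqrt(runif(1))
          lx <- avail_a * tt * cos(phi); ly <- avail_b * tt * sin(phi)
          cx <- q$cx + lx * cos(q$theta) - ly * sin(q$theta)
          cy <- q$cy + lx * sin(q$theta) + ly * cos(q$theta)
          gth <- runif(1, 0, pi)
          ok <- TRUE
          for (g in granules)
            if (sqrt((cx - g$cx)^2 + (cy - g$cy)^2) <= ga + g$a + 0.05) {
              ok <- FALSE; break
            }
          if (ok) {
            granules[[length(granules) + 1]] <- list(
              cx = cx, cy = cy, a = ga, b = gb, theta = gth, diameter = d,
              plastid_id = p,
              in_focus = runif(1) >= phenotype$out_of_focus_fraction)
            break
          }
        }
      }
    }

    # --- dense labels and instance truth (pre-blur, pre-noise) ------------
    class_labels <- matrix(CLASS_CODES[["background"]], h, w)
    class_labels[membrane] <- CLASS_CODES[["membrane"]]
    plastid_mask <- matrix(FALSE, h, w)
    for (q in pl) {
      em <- rasterize_ellipse(h, w, psz, q$cx, q$cy, q$sa, q$sb, q$theta)
      plastid_mask <- plastid_mask | em
    }
    class_labels[plastid_mask] <- CLASS_CODES[["plastid"]]
    granule_truth <- matrix(0L, h, w)
    gmasks <- vector("list", length(granules))
    for (i in seq_along(granules)) {
      g <- granules[[i]]
      gm <- rasterize_ellipse(h, w, psz, g$cx, g$cy, g$a, g$b, g$theta)
      gm <- gm & plastid_mask   # rasterization safety: stay inside plastids
      gmasks[[i]] <- gm
      granule_truth[gm] <- i
      class_labels[gm] <- CLASS_CODES[["starch"]]
    }

    truth_table <- if (length(granules))
      do.call(rbind, lapply(seq_along(granules), function(i) {
        g <- granules[[i]]
        data.frame(granule_id = i, plastid_id = g$plastid_id,
                   cx_um = g$cx, cy_um = g$cy, a_um = g$a, b_um = g$b,
                   angle = g$theta, diameter_um = g$diameter,
                   in_focus = g$in_focus)
      }))
    else data.frame(granule_id = integer(0), plastid_id = integer(0),
                    cx_um = numeric(0), cy_um = numeric(0), a_um = numeric(0),
                    b_um = numeric(0), angle = numeric(0),
                    diameter_um = numeric(0), in_focus = logical(0))

    # --- render both channels --------------------------------------------
    sharp_gr <- matrix(FALSE, h, w)
    oof_gr <- matrix(FALSE, h, w)
    for (i in seq_along(granules)) {
      if (granules[[i]]$in_focus) sharp_gr <- sharp_gr | gmasks[[i]]
      else oof_gr <- oof_gr | gmasks[[i]]
    }
    render_channel <- function(stroma_level, mem_level, bg_level) {
      tex <- gsmooth(matrix(rnorm(h * w), h), 3)
      tex <- tex / max(sd(tex), 1e-12)
      stroma <- pmax(stroma_level * (1 + render$texture_contrast * tex), 0)
      img <- matrix(bg_level, h, w)
      img[membrane] <- mem_level
      img[plastid_mask] <- stroma[plastid_mask]
      img[sharp_gr] <- stroma[sharp_gr] * render$granule_darkness
      if (any(oof_gr)) {
        ab <- gsmooth(oof_gr * 1, render$oof_extra_blur_px)
        img <- img * (1 - ab * (1 - render$oof_darkness))
      }
      img <- gsmooth(img, render$psf_sigma_px)
      img <- img + rnorm(h * w) * render$noise_gaussian_sd +
        rnorm(h * w) * sqrt(pmax(img, 0)) * render$noise_shot_scale
      pmin(pmax(img, 0), 1)
    }
    green <- render_channel(0.65, render$membrane_intensity, 0.04)
    red <- render_channel(0.85, 0.75 * render$membrane_intensity, 0.05)

    structure(list(
      image = mc_image(list(green = green, red = red),
                       pixel_size_um = psz,
                       metadata = list(synthetic = TRUE, seed = seed)),
      class_labels = as_label_map(class_labels),
      granule_truth = as_granule_labels(granule_truth, relabel = FALSE),
      granule_truth_table = truth_table,
      phenotype = phenotype, render = render, seed = seed),
      class = "synthetic_scene")
  })
}

#' In-focus-only ground truth of a scene
#'
#' Instance truth with out-of-focus granules removed — the denominator used
#' for detection-rate evaluation, mirroring the exclusion of out-of-focus
#' granules from analysis.
#'
#' @param scene A `synthetic_scene`.
#' @return Integer instance matrix (ids not renumbered).
#' @export
scene_truth_infocus <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  tr <- scene$granule_truth
  tab <- scene$granule_truth_table
  oof <- tab$granule_id[!tab$in_focus]
  tr[tr %in% oof] <- 0L
  tr
}

#' Generate a train/test benchmark of synthetic scenes
#'
#' `n_train + n_test` scenes from one phenotype; training scenes come with
#' sparse pixel labels that subsample the dense class labels (mimicking
#' partial manual labeling): per class, a fixed fraction of that class's
#' pixels, but at least `min_labels_per_class` where available, so every
#' class is present in every training label map.
#'
#' @param n_train,n_test Scene counts.
#' @param phenotype A [scene_phenotype()] or preset name.
#' @param render A [render_params()].
#' @param seed Integer seed; scene seeds are derived from it.
#' @param label_fraction Fraction of each class's pixels labeled (default
#'   0.02).
#' @param min_labels_per_class Lower bound per class and scene (default 50).
#' @return Object of class `granule_benchmark`: `train` (list of
#'   `list(scene, sparse_labels)`), `test` (list of scenes), plus the
#'   generating parameters.
#' @export
generate_benchmark <- function(n_train = 6, n_test = 4,
                               phenotype = phenotype_preset("wildtype"),
                               render = render_params(), seed = 1,
                               label_fraction = 0.02,
                               min_labels_per_class = 50) {
  if (is.character(phenotype)) phenotype <- phenotype_preset(phenotype)
  stopifnot(n_train >= 0, n_test >= 0, label_fraction > 0,
            label_fraction <= 1)
  seeds <- with_seed(seed, sample.int(2^30, n_train + n_test + 1))
  scenes <- lapply(seq_len(n_train + n_test), function(i)
    generate_scene(phenotype, render, seeds[i]))
  train <- lapply(seq_len(n_train), function(i) {
    scene <- scenes[[i]]
    sparse <- with_seed(seeds[n_train + n_test + 1] + i, {
      sl <- matrix(0L, nrow(scene$class_labels), ncol(scene$class_labels))
      for (k in 1:4) {
        idx <- which(scene$class_labels == k)
        if (length(idx) == 0) next
        n_take <- min(length(idx),
                      max(min_labels_per_class,
                          round(label_fraction * length(idx))))
        sl[sample(idx, n_take)] <- k
      }
      sl
    })
    list(scene = scene, sparse_labels = as_label_map(sparse))
  })
  structure(list(train = train, test = scenes[seq_len(n_test) + n_train],
                 phenotype = phenotype, render = render, seed = seed,
                 label_fraction = label_fraction,
                 min_labels_per_class = min_labels_per_class),
            class = "granule_benchmark")
}
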