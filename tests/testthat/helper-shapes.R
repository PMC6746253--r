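# Geometric fixtures built in code.

# Filled disk in an h x w matrix (1-based center, radius in px).
disk_mask <- function(h, w, ci, cj, r) {
  ii <- matrix(rep(seq_len(h), w), h)
  jj <- matrix(rep(seq_len(w), each = h), h)
  (ii - ci)^2 + (jj - cj)^2 <= r^2
}

# Filled rotated ellipse (semi-axes a >= b in px, angle in radians).
ellipse_mask <- function(h, w, ci, cj, a, b, theta) {
  ii <- matrix(rep(seq_len(h), w), h)
  jj <- matrix(rep(seq_len(w), each = h), h)
  u <- (jj - cj) * cos(theta) + (ii - ci) * sin(theta)
  v <- -(jj - cj) * sin(theta) + (ii - ci) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Probability maps with a given starch mask and plastid mask, confident
# everywhere (used to exercise segmentation in isolation).
maps_from_masks <- function(starch, plastid,
                            p_in = 0.95, p_bg = 0.01) {
  h <- nrow(starch); w <- ncol(starch)
  m <- array(0, dim = c(h, w, 4),
             dimnames = list(NULL, NULL, CLASS_ORDER))
  ps <- ifelse(starch, p_in, p_bg)
  pp <- ifelse(plastid & !starch, p_in, p_bg)
  pb <- pmax(1 - ps - pp - 0.01, 0)
  m[, , "starch"] <- ps
  m[, , "plastid"] <- pp
  m[, , "membrane"] <- 0.01
  m[, , "background"] <- pb
  tot <- m[, , 1] + m[, , 2] + m[, , 3] + m[, , 4]
  for (k in 1:4) m[, , k] <- m[, , k] / tot
  starchseg:::new_probability_maps(m)
}

# Small quiet scene parameters for fast unit tests.
quiet_render <- function(...) render_params(
  image_size_px = 160, noise_gaussian_sd = 0, noise_shot_scale = 0, ...)

small_phenotype <- function(...) scene_phenotype(
  plastids_per_image = c(2, 3), plastid_diameter_um = c(4, 5.5), ...)
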