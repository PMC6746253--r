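test_that("probability thresholding is inclusive and handles boundaries", {
  m <- array(0, c(4, 4, 4), dimnames = list(NULL, NULL, CLASS_ORDER))
  m[, , "starch"] <- matrix(c(0.79, 0.80, 0.81, 1), 4, 4)
  m[, , "background"] <- 1 - m[, , "starch"]
  maps <- starchseg:::new_probability_maps(m)
  mask <- threshold_probability(maps, "starch", 0.80)
  expect_identical(mask[, 1], c(FALSE, TRUE, TRUE, TRUE))
  expect_false(any(threshold_probability(maps, "starch", 2)))
  expect_true(all(threshold_probability(maps, "starch", 1e-9)))
  expect_error(threshold_probability(maps, "vacuole"), "unknown")
})

test_that("embedding keeps plastid-internal granules, drops background decoys", {
  h <- 80; w <- 80
  plastid <- disk_mask(h, w, 30, 30, 20)
  granule <- disk_mask(h, w, 30, 30, 5)       # fully inside the plastid
  decoy <- disk_mask(h, w, 65, 65, 5)         # sits on dark background
  starch <- granule | decoy
  plastid_only <- plastid & !granule
  out <- enforce_embedding(starch, plastid_only, segmentation_params())
  expect_true(all(out[granule]))
  expect_false(any(out[decoy]))
  expect_equal(attr(out, "removed"), 1L)
  expect_error(enforce_embedding(starch, plastid[1:10, ]), "shape")
})

test_that("embedding boundary fraction is inclusive at the threshold", {
  # component = one 10 px row segment; boundary enumerated by brute force
  h <- 20; w <- 30
  starch <- matrix(FALSE, h, w)
  starch[10, 11:20] <- TRUE
  dil <- EBImage::imageData(EBImage::dilate(starch * 1, matrix(1, 3, 3))) > 0
  boundary <- which(dil & !starch)
  n_b <- length(boundary)
  expect_equal(n_b, 3 * 12 - 10)              # sanity of the oracle itself
  for (target in c(0.80, 0.75)) {
    n_in <- ceiling(n_b * target)
    plastid <- matrix(FALSE, h, w)
    plastid[boundary[seq_len(n_in)]] <- TRUE
    frac <- n_in / n_b
    out <- enforce_embedding(starch, plastid,
                             segmentation_params(fill_holes = FALSE,
                                                 plastid_close_radius = 0))
    if (frac >= 0.8) expect_true(all(out[starch]))
    else expect_false(any(out))
  }
})

test_that("watershed splits touching disks and conserves pixels", {
  h <- 40; w <- 60
  single <- disk_mask(h, w, 20, 20, 8)
  lab1 <- split_touching(single, segmentation_params())
  expect_equal(max(lab1), 1L)
  expect_identical(lab1 > 0, single)

  two <- disk_mask(h, w, 20, 20, 8) | disk_mask(h, w, 20, 32, 8)
  lab2 <- split_touching(two, segmentation_params())
  expect_equal(max(lab2), 2L)
  expect_identical(lab2 > 0, two)          # exact pixel conservation
  expect_equal(sum(lab2 == 1L) + sum(lab2 == 2L), sum(two))

  empty <- split_touching(matrix(FALSE, 10, 10), segmentation_params())
  expect_equal(max(empty), 0L)
  expect_equal(dim(empty), c(10L, 10L))

  # watershed disabled: connected components only
  lab_cc <- split_touching(two, segmentation_params(watershed_enabled = FALSE))
  expect_equal(max(lab_cc), 1L)
})

test_that("particle filtering enforces area and edge rules inclusively", {
  lab <- matrix(0L, 30, 30)
  lab[5:6, 5] <- 1L            # 2 px (order: first encountered scanning rows)
  lab[10, 10:12] <- 2L         # 3 px -> below min_area 4
  lab[15:16, 15:16] <- 3L      # exactly 4 px -> kept (inclusive)
  lab[1, 20:25] <- 4L          # touches row 1 -> edge-removed
  lab[20:24, 20:24] <- 5L      # interior, kept
  out <- filter_particles(lab, segmentation_params())
  expect_equal(max(out), 2L)
  expect_equal(attr(out, "removed_small"), 2L)
  expect_equal(attr(out, "removed_edge"), 1L)
  # survivors renumbered in top-left-first scan order
  expect_true(all(out[15:16, 15:16] == 1L))
  expect_true(all(out[20:24, 20:24] == 2L))

  keep_edges <- filter_particles(lab,
                                 segmentation_params(exclude_edge_particles = FALSE))
  expect_equal(attr(keep_edges, "removed_edge"), 0L)
  expect_equal(max(keep_edges), 3L)
})

test_that("segment_granules composes stages monotonically and logs removals", {
  h <- 100; w <- 100
  plastid <- disk_mask(h, w, 40, 40, 25) | disk_mask(h, w, 75, 75, 18)
  g1 <- disk_mask(h, w, 35, 35, 5)
  g2 <- disk_mask(h, w, 35, 45, 5)            # touches g1 after threshold
  g3 <- disk_mask(h, w, 75, 75, 4)
  tiny <- matrix(FALSE, h, w); tiny[50, 60] <- TRUE   # 1 px inside plastid?
  decoy <- disk_mask(h, w, 10, 85, 4)
  starch <- g1 | g2 | g3 | decoy | tiny
  maps <- maps_from_masks(starch, plastid & !starch)
  res <- segment_granules(maps, segmentation_params())
  expect_s3_class(res, "segmentation_result")
  # the decoy is logged as not embedded, the 1 px speck as too small
  expect_equal(res$exclusion_log$not_embedded, 1L)
  expect_equal(res$exclusion_log$too_small, 1L)
  expect_equal(res$n_granules, 3L)
  # monotonicity: every granule pixel was in the thresholded starch mask
  expect_true(all(starch[res$granules > 0]))
  # determinism
  res2 <- segment_granules(maps, segmentation_params())
  expect_identical(res$granules, res2$granules)

  blank <- maps_from_masks(matrix(FALSE, 20, 20), matrix(FALSE, 20, 20))
  res0 <- segment_granules(blank, segmentation_params())
  expect_equal(res0$n_granules, 0L)
})
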