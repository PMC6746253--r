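test_that("single pixel and analytic shapes measure correctly", {
  m <- matrix(0L, 10, 10); m[5, 5] <- 1L
  tab <- measure_granules(m, 0.1)$measurements
  expect_equal(tab$area_um2, 0.01)
  expect_equal(tab$equiv_diameter_um, 2 * sqrt(0.01 / pi))  # ~0.1128
  expect_equal(tab$centroid_x_px, 4)  # 0-based column
  expect_equal(tab$centroid_y_px, 4)
  expect_gt(tab$major_um, 0)
  expect_gte(tab$major_um, tab$minor_um)

  # disk of radius 20 px at pixel size 1
  d <- matrix(0L, 61, 61); d[disk_mask(61, 61, 31, 31, 20)] <- 1L
  td <- measure_granules(d, 1)$measurements
  expect_equal(td$area_um2, pi * 400, tolerance = 0.02)
  expect_equal(td$major_um, 40, tolerance = 0.03)
  expect_equal(td$minor_um, 40, tolerance = 0.03)
  expect_equal(td$perimeter_um, 2 * pi * 20, tolerance = 0.05)
  expect_equal(td$equiv_diameter_um, 2 * sqrt(td$area_um2 / pi))

  # ellipse semi-axes (30, 10) px rotated 37 degrees
  e <- matrix(0L, 101, 101)
  e[ellipse_mask(101, 101, 51, 51, 30, 10, 37 * pi / 180)] <- 1L
  te <- measure_granules(e, 1)$measurements
  expect_equal(te$major_um, 60, tolerance = 0.03)
  expect_equal(te$minor_um, 20, tolerance = 0.03)
})

test_that("pixel size scales areas quadratically and lengths linearly", {
  set.seed(5)
  m <- matrix(0L, 50, 50)
  m[ellipse_mask(50, 50, 25, 25, 12, 7, 0.4)] <- 1L
  m[disk_mask(50, 50, 10, 40, 5) & m == 0] <- 2L
  t1 <- measure_granules(m, 0.1)$measurements
  t2 <- measure_granules(m, 0.2)$measurements
  expect_equal(t2$area_um2, 4 * t1$area_um2)
  for (cc in c("perimeter_um", "major_um", "minor_um", "equiv_diameter_um"))
    expect_equal(t2[[cc]], 2 * t1[[cc]], label = cc)
})

test_that("area is invariant and perimeter stable under 90-degree rotation", {
  m <- matrix(0L, 60, 80)
  m[ellipse_mask(60, 80, 30, 40, 18, 9, 0.7)] <- 1L
  rot <- t(m)[, nrow(m):1]
  a <- measure_granules(m, 1)$measurements
  b <- measure_granules(rot, 1)$measurements
  expect_equal(a$area_um2, b$area_um2)
  expect_equal(a$perimeter_um, b$perimeter_um, tolerance = 0.05)
  expect_equal(a$major_um, b$major_um, tolerance = 1e-6)
})

test_that("summaries: hand-computed SE, single-granule convention, empty", {
  tab <- structure(list(measurements = data.frame(
    granule_id = 1:3, area_um2 = c(1, 2, 3), perimeter_um = c(1, 1, 1),
    major_um = c(1, 1, 1), minor_um = c(1, 1, 1),
    equiv_diameter_um = c(1, 1, 1), centroid_x_px = 0, centroid_y_px = 0),
    image_id = "x", pixel_size_um = 1), class = "granule_table")
  s <- summarize_granules(tab)$stats
  expect_equal(s$mean[s$parameter == "area_um2"], 2)
  expect_equal(s$standard_error[s$parameter == "area_um2"], 1 / sqrt(3))
  expect_equal(s$standard_error[s$parameter == "perimeter_um"], 0)

  single <- measure_granules({m <- matrix(0L, 9, 9); m[4:6, 4:6] <- 1L; m}, 1)
  expect_true(all(summarize_granules(single)$stats$standard_error == 0))

  empty <- measure_granules(matrix(0L, 5, 5), 1)
  expect_equal(nrow(summarize_granules(empty)$stats), 0)
})

test_that("size histograms conserve counts and find the generating mode", {
  tab <- measure_granules(matrix(0L, 5, 5), 1)
  tab$measurements <- data.frame(
    granule_id = 1:10, area_um2 = rep(0.55, 10), perimeter_um = 1,
    major_um = 1, minor_um = 1, equiv_diameter_um = 1,
    centroid_x_px = 0, centroid_y_px = 0)
  h <- size_distribution(tab, "area_um2", 0.2)
  expect_equal(sum(h$counts), 10)
  expect_equal(sum(h$counts > 0), 1)

  set.seed(99)
  areas <- rnorm(500, mean = 2.5, sd = 0.3)
  tab$measurements <- data.frame(
    granule_id = 1:500, area_um2 = areas, perimeter_um = 1, major_um = 1,
    minor_um = 1, equiv_diameter_um = 1, centroid_x_px = 0, centroid_y_px = 0)
  h2 <- size_distribution(tab, "area_um2", 0.2)
  expect_equal(sum(h2$counts), 500)
  mode_center <- h2$breaks[which.max(h2$counts)] + 0.1
  expect_lt(abs(mode_center - 2.5), 0.2 + 1e-9)

  h0 <- size_distribution(measure_granules(matrix(0L, 5, 5), 1))
  expect_equal(sum(h0$counts), 0)
})

test_that("population comparison: identical tables give t = 0, p = 1", {
  m <- matrix(0L, 40, 40)
  m[disk_mask(40, 40, 10, 10, 4)] <- 1L
  m[disk_mask(40, 40, 25, 25, 6) & m == 0] <- 2L
  m[disk_mask(40, 40, 10, 30, 5) & m == 0] <- 3L
  tab <- measure_granules(m, 0.1)
  cmp <- compare_populations(tab, tab, "area_um2")
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  empty <- measure_granules(matrix(0L, 5, 5), 1)
  expect_error(compare_populations(tab, empty), "empty")
})
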