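test_that("phenotype presets carry the documented biology", {
  wt <- phenotype_preset("wildtype")
  expect_equal(wt$granules_per_plastid, c(5L, 7L))
  expect_equal(wt$granule_diameter_um$mean, 0.9)
  expect_equal(wt$granule_diameter_um$lo, 0.8)
  expect_equal(wt$granule_diameter_um$hi, 1.0)
  ss4 <- phenotype_preset("ss4")
  expect_lte(ss4$granules_per_plastid[2], 2L)
  expect_gt(ss4$granule_diameter_um$mean, wt$granule_diameter_um$mean)
  expect_error(phenotype_preset("amylose"), "wildtype")
})

test_that("scenes are seeded-deterministic and internally consistent", {
  s1 <- generate_scene(small_phenotype(), quiet_render(), seed = 7)
  s2 <- generate_scene(small_phenotype(), quiet_render(), seed = 7)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$granule_truth, s2$granule_truth)

  # every granule pixel is starch class; granules sit inside plastid regions
  gt <- s1$granule_truth
  expect_true(all(s1$class_labels[gt > 0] == CLASS_CODES[["starch"]]))
  grown <- EBImage::imageData(EBImage::dilate((gt > 0) * 1, matrix(1, 3, 3)))
  ring <- grown > 0 & gt == 0
  expect_true(all(s1$class_labels[ring] %in%
                    CLASS_CODES[c("plastid", "starch")]))
  expect_equal(sort(unique(gt[gt > 0])),
               seq_len(nrow(s1$granule_truth_table)))
})

test_that("impossible plastid packings raise a helpful error", {
  ph <- scene_phenotype(plastids_per_image = c(6, 6),
                        plastid_diameter_um = c(7, 7))
  small <- render_params(image_size_px = 100)  # 10 um field
  expect_error(generate_scene(ph, small, seed = 1), "fewer or smaller")
})

test_that("an empty phenotype renders a granule-free scene", {
  ph <- scene_phenotype(plastids_per_image = c(0, 0))
  sc <- generate_scene(ph, quiet_render(), seed = 3)
  expect_equal(max(sc$granule_truth), 0)
  expect_equal(nrow(sc$granule_truth_table), 0)
  expect_true(all(sc$class_labels %in%
                    CLASS_CODES[c("membrane", "background")]))
})

test_that("measuring the ground truth recovers the generating sizes", {
  tabs <- lapply(1:4, function(i) {
    sc <- generate_scene("wildtype", render_params(), seed = 100 + i)
    measure_granules(sc$granule_truth, sc$image$pixel_size_um)
  })
  tab <- bind_granule_tables(tabs)
  d <- tab$measurements$equiv_diameter_um
  expect_gt(length(d), 50)
  # generator/measurer cross-check: mean within 3 sd of the 0.9 um target
  expect_lt(abs(mean(d) - 0.9), 3 * 0.05)
  # per-granule ellipse area recovered within rasterization error
  # per-granule ellipse areas: quantization of a ~9 px disk allows ~10%
  # scatter at 0.1 um/px, but the bias averages out across granules
  sc <- generate_scene("wildtype", render_params(), seed = 100)
  tt <- sc$granule_truth_table
  meas <- measure_granules(sc$granule_truth, sc$image$pixel_size_um)$measurements
  rel_err <- vapply(seq_len(nrow(tt)), function(k) {
    expected <- pi * tt$a_um[k] * tt$b_um[k]
    got <- meas$area_um2[meas$granule_id == tt$granule_id[k]]
    (got - expected) / expected
  }, 0)
  expect_lt(max(abs(rel_err)), 0.10)
  expect_lt(abs(mean(rel_err)), 0.03)
})

test_that("granule interiors are darker than plastid stroma in both channels", {
  for (seed in c(5, 6)) {
    sc <- generate_scene(small_phenotype(), quiet_render(), seed = seed)
    gt <- sc$granule_truth > 0
    stroma <- sc$class_labels == CLASS_CODES[["plastid"]]
    for (ch in names(sc$image$pixels)) {
      px <- sc$image$pixels[[ch]]
      expect_lt(mean(px[gt]), mean(px[stroma]))
    }
  }
})

test_that("benchmarks split scenes and label every class in training maps", {
  b <- generate_benchmark(n_train = 2, n_test = 1,
                          phenotype = small_phenotype(),
                          render = quiet_render(), seed = 9)
  expect_length(b$train, 2)
  expect_length(b$test, 1)
  for (tr in b$train) {
    sl <- tr$sparse_labels
    expect_true(all(1:4 %in% unique(as.vector(sl))))
    # sparse labels agree with the dense truth wherever set
    set_px <- sl > 0
    expect_true(all(sl[set_px] == tr$scene$class_labels[set_px]))
  }
  b2 <- generate_benchmark(n_train = 2, n_test = 1,
                           phenotype = small_phenotype(),
                           render = quiet_render(), seed = 9)
  expect_identical(b$train[[1]]$sparse_labels, b2$train[[1]]$sparse_labels)
  expect_identical(b$test[[1]]$image$pixels, b2$test[[1]]$image$pixels)
})

test_that("wild-type and ss4 ground-truth areas separate sharply", {
  harvest_truth <- function(preset, seeds) {
    tabs <- lapply(seeds, function(s) {
      sc <- generate_scene(preset, render_params(), seed = s)
      measure_granules(sc$granule_truth, sc$image$pixel_size_um)
    })
    bind_granule_tables(tabs)
  }
  wt <- harvest_truth("wildtype", 301:304)
  ss4 <- harvest_truth("ss4", 401:430)
  expect_gte(nrow(wt$measurements), 100)
  expect_gte(nrow(ss4$measurements), 100)
  cmp <- compare_populations(ss4, wt, "area_um2")
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$mean_a, cmp$mean_b)   # ss4 granules are larger
})
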