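# Small, fast feature configuration for classifier unit tests.
tiny_features <- function() feature_config(
  families = c("gaussian_blur", "mean", "variance"), sigmas = c(1, 2, 4))

feature_matrix_of <- function(img)
  starchseg:::feature_matrix(compute_feature_stack(img, tiny_features()))

noiseless_pair <- function(seed = 21) {
  scene <- generate_scene(small_phenotype(), quiet_render(), seed = seed)
  sparse <- with(list(cl = scene$class_labels), {
    set.seed(seed + 1)
    sl <- matrix(0L, nrow(cl), ncol(cl))
    for (k in 1:4) {
      idx <- which(cl == k)
      sl[sample(idx, min(length(idx), 200))] <- k
    }
    sl
  })
  list(scene = scene, sparse = sparse)
}

test_that("training on a separable scene beats 95%, like a centroid oracle", {
  np <- noiseless_pair()
  img <- enhance(np$scene$image)
  model <- train_classifier(list(list(image = img, labels = np$sparse)),
                            tiny_features(),
                            classifier_config(n_trees = 100, seed = 3))
  expect_equal(model$training_summary$n_images, 1)
  maps <- predict_probabilities(model, img)
  pred <- apply(maps$maps, c(1, 2), which.max)
  held_out <- np$scene$class_labels > 0 & np$sparse == 0
  acc <- mean(pred[held_out] == np$scene$class_labels[held_out])
  expect_gt(acc, 0.95)

  # independent oracle: nearest-centroid on the same features also separates
  fs <- feature_matrix_of(img)
  lab <- np$sparse
  centroids <- vapply(1:4, function(k)
    colMeans(fs[lab == k, , drop = FALSE]), numeric(ncol(fs)))
  d2 <- vapply(1:4, function(k)
    rowSums(sweep(fs, 2, centroids[, k])^2), numeric(nrow(fs)))
  nc_pred <- max.col(-d2)
  nc_acc <- mean(nc_pred[held_out] == np$scene$class_labels[held_out])
  expect_gt(nc_acc, 0.9)
})

test_that("training and prediction are deterministic given the seed", {
  np <- noiseless_pair(31)
  img <- enhance(np$scene$image)
  pair <- list(list(image = img, labels = np$sparse))
  m1 <- train_classifier(pair, tiny_features(), classifier_config(seed = 9))
  m2 <- train_classifier(pair, tiny_features(), classifier_config(seed = 9))
  expect_identical(predict_probabilities(m1, img)$maps,
                   predict_probabilities(m2, img)$maps)
})

test_that("probability maps are normalized, even on blank images", {
  np <- noiseless_pair(41)
  img <- enhance(np$scene$image)
  model <- train_classifier(list(list(image = img, labels = np$sparse)),
                            tiny_features(),
                            classifier_config(n_trees = 50, seed = 5))
  sums <- apply(predict_probabilities(model, img)$maps, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)

  blank <- mc_image(list(matrix(0, 64, 64), matrix(0, 64, 64)),
                    pixel_size_um = 0.1)
  bm <- predict_probabilities(model, blank)$maps
  expect_true(all(is.finite(bm)))
  expect_lt(max(abs(apply(bm, c(1, 2), sum) - 1)), 1e-6)

  one_ch <- mc_image(matrix(0.5, 32, 32), pixel_size_um = 0.1)
  expect_error(predict_probabilities(model, one_ch), "channel")
})

test_that("a class with no labeled pixels is named in the error", {
  np <- noiseless_pair(51)
  lab <- np$sparse
  lab[lab == 1L] <- 0L  # wipe out the starch labels
  expect_error(
    train_classifier(list(list(image = np$scene$image, labels = lab)),
                     tiny_features()),
    "starch")
  bad_shape <- matrix(0L, 4, 4)
  expect_error(
    train_classifier(list(list(image = np$scene$image, labels = bad_shape)),
                     tiny_features()),
    "shape")
})

test_that("detection metrics follow the greedy >=50% overlap rule", {
  truth <- matrix(0L, 40, 60)
  truth[5:10, 5:10] <- 1L
  truth[20:29, 10:19] <- 2L
  truth[5:14, 40:49] <- 3L

  ident <- evaluate_detection(truth, truth)
  expect_equal(ident$detection_rate, 1.0)
  expect_equal(ident$n_false_positive, 0L)

  none <- evaluate_detection(matrix(0L, 40, 60), truth)
  expect_equal(none$detection_rate, 0.0)
  expect_equal(none$n_true_granules, 3L)

  # covers granules 1 and 2 fully, granule 3 at 30% of its pixels
  pred <- matrix(0L, 40, 60)
  pred[truth == 1L] <- 1L
  pred[truth == 2L] <- 2L
  idx3 <- which(truth == 3L)
  pred[idx3[seq_len(30)]] <- 3L   # 30 of 100 px
  # oracle by explicit pixel counting
  expect_equal(sum(pred == 3L & truth == 3L) / sum(truth == 3L), 0.3)
  part <- evaluate_detection(pred, truth, min_overlap = 0.5)
  expect_equal(part$n_matched, 2L)
  expect_equal(part$detection_rate, 2 / 3)

  expect_error(evaluate_detection(matrix(0L, 2, 2), truth), "shape")
})
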