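# Four-class random-forest pixel classification: training from sparsely
# labeled images, per-class probability maps, and object-level detection
# evaluation against ground truth.

#' Random-forest classifier configuration
#'
#' @param n_trees Number of trees (default 200).
#' @param max_features_per_split Features tried at each split; `"sqrt"`
#'   (default) uses the square root of the feature count, or give an integer.
#' @param seed RNG seed recorded in the trained model (default 42).
#' @param balanced_subsample Draw equally many training pixels per class
#'   (down-sampling the majority classes). Default FALSE: no reweighting.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 200, max_features_per_split = "sqrt",
                              seed = 42, balanced_subsample = FALSE) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_features_per_split = max_features_per_split,
                 seed = as.integer(seed),
                 balanced_subsample = isTRUE(balanced_subsample),
                 class_order = CLASS_ORDER),
            class = "classifier_config")
}

new_probability_maps <- function(maps, class_order = CLASS_ORDER,
                                 source_image_id = NA_character_) {
  structure(list(maps = maps, class_order = class_order,
                 source_image_id = source_image_id),
            class = "probability_maps")
}

#' Train the pixel classifier from sparsely labeled images
#'
#' Computes the feature stack of every image and fits a probability random
#' forest on the feature vectors of labeled pixels only (label code 0 =
#' unlabeled is excluded). Every one of the four classes must have at least
#' one labeled pixel across the training set. Deterministic given the seed.
#'
#' @param pairs List of `list(image = mc_image, labels = label matrix)`.
#' @param feature_config A [feature_config()].
#' @param classifier_config A [classifier_config()].
#' @return Object of class `trained_classifier` with elements `forest`,
#'   `feature_config`, `classifier_config`, `n_channels` and
#'   `training_summary` (per-class labeled-pixel counts, image count, and
#'   out-of-bag accuracy).
#' @export
train_classifier <- function(pairs, feature_config = starchseg::feature_config(),
                             classifier_config = starchseg::classifier_config()) {
  stopifnot(length(pairs) >= 1)
  xs <- list(); ys <- list()
  nch <- NULL
  for (p in pairs) {
    assert_mc_image(p$image)
    labels <- as_label_map(p$labels, p$image)
    nch_i <- length(feature_config$channels_used %||% names(p$image$pixels))
    if (is.null(nch)) nch <- nch_i
    else if (nch != nch_i) stop("training images differ in channel count")
    sel <- which(labels > 0)
    if (length(sel) == 0) next
    stack <- compute_feature_stack(p$image, feature_config)
    xs[[length(xs) + 1]] <- feature_matrix(stack)[sel, , drop = FALSE]
    ys[[length(ys) + 1]] <- labels[sel]
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  counts <- vapply(1:4, function(k) sum(y == k), 0L)
  names(counts) <- CLASS_ORDER
  if (is.null(x) || any(counts == 0))
    stop(sprintf("no labeled pixels for class(es): %s",
                 paste(CLASS_ORDER[counts == 0 | is.null(x)], collapse = ", ")))
  if (classifier_config$balanced_subsample) {
    n_min <- min(counts)
    keep <- with_seed(classifier_config$seed, unlist(lapply(1:4, function(k) {
      idx <- which(y == k)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    })))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  yf <- factor(CLASS_ORDER[y], levels = CLASS_ORDER)
  mtry <- if (identical(classifier_config$max_features_per_split, "sqrt"))
    max(1L, floor(sqrt(ncol(x)))) else
    as.integer(classifier_config$max_features_per_split)
  forest <- ranger::ranger(x = x, y = yf,
                           num.trees = classifier_config$n_trees,
                           mtry = mtry, probability = TRUE,
                           seed = classifier_config$seed, num.threads = 1,
                           verbose = FALSE)
  oob_class <- CLASS_ORDER[max.col(forest$predictions)]
  structure(list(forest = forest,
                 feature_config = feature_config,
                 classifier_config = classifier_config,
                 n_channels = nch,
                 feature_names = colnames(x),
                 training_summary = list(
                   n_labeled_pixels = counts,
                   n_images = length(pairs),
                   oob_accuracy = mean(oob_class == as.character(yf)))),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  s <- x$training_summary
  cat(sprintf(paste0("<trained_classifier> %d trees, %d features, ",
                     "%d training image(s)\n  labeled px: %s\n  ",
                     "out-of-bag accuracy: %.3f\n"),
              x$classifier_config$n_trees, length(x$feature_names),
              s$n_images,
              paste(sprintf("%s=%d", names(s$n_labeled_pixels),
                            s$n_labeled_pixels), collapse = ", "),
              s$oob_accuracy))
  invisible(x)
}

#' Predict per-class probability maps
#'
#' Per-pixel class probabilities are the forest's vote fractions; at every
#' pixel the four values are non-negative and sum to 1.
#'
#' @param model A `trained_classifier`.
#' @param image An [mc_image()] with the channel count the model was
#'   trained on (typically after [enhance()]).
#' @param image_id Identifier stored in the result.
#' @return Object of class `probability_maps`: `maps` (height x width x 4
#'   array in class order), `class_order`, `source_image_id`.
#' @export
predict_probabilities <- function(model, image, image_id = NA_character_) {
  stopifnot(inherits(model, "trained_classifier"))
  assert_mc_image(image)
  nch <- length(model$feature_config$channels_used %||% names(image$pixels))
  if (nch != model$n_channels)
    stop(sprintf("image has %d usable channel(s) but model expects %d",
                 nch, model$n_channels))
  stack <- compute_feature_stack(image, model$feature_config)
  m <- feature_matrix(stack)
  if (!identical(colnames(m), model$feature_names))
    stop("feature stack names do not match the model's feature configuration")
  pr <- predict(model$forest, m, num.threads = 1)$predictions
  pr <- pr[, CLASS_ORDER, drop = FALSE]
  d <- dim(image)
  maps <- array(pr, dim = c(d[1], d[2], 4),
                dimnames = list(NULL, NULL, CLASS_ORDER))
  new_probability_maps(maps, CLASS_ORDER, image_id)
}

#' Object-level detection metrics
#'
#' A true granule counts as detected when some predicted instance covers at
#' least `min_overlap` of its pixels; matching is greedy one-to-one, largest
#' pixel overlap first. Unmatched predicted instances are false positives.
#'
#' @param predicted,truth Granule instance label matrices of the same shape.
#' @param min_overlap Required fraction of a true granule's pixels covered
#'   by its matched prediction (default 0.5, inclusive).
#' @return List of class `detection_metrics`: `n_true_granules`,
#'   `n_matched`, `n_false_positive`, `detection_rate`, `match_criterion`.
#' @export
evaluate_detection <- function(predicted, truth, min_overlap = 0.5) {
  if (!all(dim(predicted) == dim(truth))) stop("shape mismatch")
  predicted <- as_granule_labels(predicted, relabel = FALSE)
  truth <- as_granule_labels(truth, relabel = FALSE)
  t_ids <- sort(unique(truth[truth > 0]))
  p_ids <- sort(unique(predicted[predicted > 0]))
  t_size <- tabulate(truth[truth > 0], nbins = max(truth, 1))
  sel <- truth > 0 & predicted > 0
  matched_t <- integer(0); matched_p <- integer(0)
  if (any(sel)) {
    ov <- as.data.frame(table(t = truth[sel], p = predicted[sel]),
                        stringsAsFactors = FALSE)
    ov <- ov[ov$Freq > 0, , drop = FALSE]
    ov$t <- as.integer(ov$t); ov$p <- as.integer(ov$p)
    ov <- ov[order(-ov$Freq), , drop = FALSE]
    for (r in seq_len(nrow(ov))) {
      ti <- ov$t[r]; pi <- ov$p[r]
      if (ti %in% matched_t || pi %in% matched_p) next
      if (ov$Freq[r] / t_size[ti] >= min_overlap) {
        matched_t <- c(matched_t, ti)
        matched_p <- c(matched_p, pi)
      }
    }
  }
  n_true <- length(t_ids)
  structure(list(
    n_true_granules = n_true,
    n_matched = length(matched_t),
    n_false_positive = length(setdiff(p_ids, matched_p)),
    detection_rate = length(matched_t) / max(n_true, 1),
    match_criterion = sprintf(
      "greedy one-to-one, largest pixel overlap first, >= %g of truth pixels",
      min_overlap)),
    class = "detection_metrics")
}
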