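#' @title Occlusion importance, concept classification and concept scores
#' @description The explanation stack. A region's importance index is the
#'   signed change in the predicted probability when the region is occluded —
#'   here by removing its tiles from the bag, the faithful analogue of
#'   occluding all pixels for a model that consumes tile features. Regions
#'   whose (by default min-max normalized) importance exceeds 0.7 are scored
#'   against seven pathology concepts by a patch classifier, and per-concept
#'   relevance is scaled to \[0, 100\] with 100 marking the most relevant
#'   concept.
#' @name interpret
NULL

#' Occlusion importance map
#'
#' For each region (tile), `importance = p(target | full bag) - p(target |
#' bag without the region's tiles)`. Deterministic in eval mode. For a
#' single-tile slide the occluded prediction falls back to the uniform prior
#' `1 / n_classes`. The `importance_norm` column min-max rescales the signed
#' importance to \[0, 1\] (all-equal maps normalize to 0).
#'
#' @param model A trained `mil_model`.
#' @param bag A `feature_bag`.
#' @param assignment Matching `cluster_assignment`.
#' @param target_class 1-based class whose probability is tracked (default 2,
#'   the positive class of a binary task).
#' @param forward_fn Forward function `(model, bag, cluster_ids)` returning a
#'   list with `class_probabilities`; defaults to [mil_forward()]. Surrogate
#'   models (e.g. a linear-logit pooling model with a closed-form occlusion
#'   delta) can be plugged in here.
#' @param n_classes Number of classes (taken from `model$config` when absent).
#' @return data.frame with `slide_id`, `tile_id`, `grid_row`, `grid_col`,
#'   `importance` (in \[-1, 1\]) and `importance_norm`.
#' @export
occlusion_importance <- function(model, bag, assignment, target_class = 2,
                                 forward_fn = mil_forward,
                                 n_classes = NULL) {
  n <- nrow(bag$features)
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster_id else assignment
  n_classes <- n_classes %||% model$config$n_classes
  p_full <- forward_fn(model, bag, cl)$class_probabilities[target_class]
  imp <- numeric(n)
  for (i in seq_len(n)) {
    if (n == 1) {
      p_occ <- 1 / n_classes
    } else {
      keep <- setdiff(seq_len(n), i)
      sub <- bag
      sub$features <- bag$features[keep, , drop = FALSE]
      sub$tile_ids <- bag$tile_ids[keep]
      p_occ <- forward_fn(model, sub, cl[keep])$class_probabilities[target_class]
    }
    imp[i] <- p_full - p_occ
  }
  rng <- range(imp)
  norm <- if (diff(rng) > 0) (imp - rng[1]) / diff(rng) else rep(0, n)
  rc <- parse_tile_ids(bag$tile_ids)
  data.frame(slide_id = bag$slide_id, tile_id = bag$tile_ids,
             grid_row = rc$row, grid_col = rc$col,
             importance = imp, importance_norm = norm)
}

parse_tile_ids <- function(ids) {
  m <- regmatches(ids, regexec("r([0-9]+)_c([0-9]+)", ids))
  list(row = vapply(m, function(x) as.integer(x[2]), integer(1)),
       col = vapply(m, function(x) as.integer(x[3]), integer(1)))
}

# simple filter statistics of an RGB patch: per-channel mean/sd, edge density,
# and mean/sd of fixed random 3x3 convolution responses on the gray image
concept_patch_features <- function(pixels, filters) {
  x <- pixels / 255
  gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  gx <- abs(gray[, -1] - gray[, -ncol(gray)])
  gy <- abs(gray[-1, ] - gray[-nrow(gray), ])
  stats <- c(mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3]),
             sd(as.vector(x[, , 1])), sd(as.vector(x[, , 2])),
             sd(as.vector(x[, , 3])),
             mean(gx > 0.05), mean(gy > 0.05), mean(gx), mean(gy))
  for (k in filters) {
    r <- EBImage::filter2(gray, k)
    r[r < 0] <- 0
    stats <- c(stats, mean(r), sd(as.vector(r)))
  }
  stats
}

concept_filters <- function(seed = 97, n = 6) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    k <- matrix(rnorm(9), 3, 3); k - mean(k)
  }))
}

#' Train the seven-concept patch classifier
#'
#' A small convolutional classifier: a fixed random 3x3 filter bank plus
#' channel/edge statistics feed a multinomial logistic head
#' (`nnet::multinom`) trained under a fixed seed. Held-out accuracy is
#' reported when a validation set is supplied.
#'
#' @param patches List of RGB patches (0-255 arrays).
#' @param labels Concept code per patch (values from [concept_names()]).
#' @param seed Integer seed fixing the filter bank.
#' @param val_patches,val_labels Optional held-out set.
#' @return A `concept_model`: list with the fitted head, `filters`, `levels`,
#'   and `val_accuracy` (NA without a validation set).
#' @export
train_concept_classifier <- function(patches, labels, seed = 1,
                                     val_patches = NULL, val_labels = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("at least 2 concepts required")
  if (!all(labels %in% concept_names())) stop("unknown concept label")
  filters <- concept_filters(seed)
  feat <- t(vapply(patches, concept_patch_features, numeric(10 + 12),
                   filters = filters))
  df <- data.frame(y = factor(labels, levels = concept_names()), feat)
  fit <- with_seed(seed, nnet::multinom(y ~ ., data = df, maxit = 400,
                                        trace = FALSE))
  model <- structure(list(fit = fit, filters = filters,
                          levels = concept_names(), val_accuracy = NA_real_),
                     class = "concept_model")
  if (!is.null(val_patches)) {
    pred <- predict_concepts(model, val_patches)
    model$val_accuracy <- mean(pred$concept == as.character(val_labels))
  }
  model
}

#' Classify patches into pathology concepts
#'
#' @param model A `concept_model`.
#' @param patches List of RGB patches.
#' @return List with `concept` (predicted code per patch) and `prob`
#'   (n x 7 probability matrix, columns ordered as [concept_names()]).
#' @export
predict_concepts <- function(model, patches) {
  feat <- t(vapply(patches, concept_patch_features, numeric(10 + 12),
                   filters = model$filters))
  df <- data.frame(feat)
  pr <- predict(model$fit, newdata = df, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, names(pr)))
  full <- matrix(0, nrow(pr), length(model$levels),
                 dimnames = list(NULL, model$levels))
  full[, colnames(pr)] <- pr
  list(concept = model$levels[max.col(full, ties.method = "first")],
       prob = full)
}

#' Concept scores over high-importance regions
#'
#' Regions whose importance exceeds `threshold` (on the min-max normalized
#' scale by default; `scale = "raw"` uses the signed probability change) are
#' selected; each concept's raw score is the importance-weighted sum of the
#' concept probabilities over the selected regions, and raw scores are scaled
#' so the maximum equals 100. When no region is selected, or all raw scores
#' are zero, all-zero scores are returned with a warning.
#'
#' @param map Importance map from [occlusion_importance()].
#' @param concept_probs n_regions x 7 probability matrix aligned to the map's
#'   rows (from [predict_concepts()]).
#' @param threshold Selection threshold (default 0.7).
#' @param scale `"normalized"` (default) or `"raw"`.
#' @return Named numeric vector over [concept_names()], values in \[0, 100\].
#' @export
concept_scores <- function(map, concept_probs, threshold = 0.7,
                           scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  imp <- if (scale == "normalized") map$importance_norm else map$importance
  sel <- which(imp > threshold)
  out <- setNames(rep(0, length(concept_names())), concept_names())
  if (length(sel) == 0) {
    warning("no region exceeds the importance threshold; all-zero scores")
    return(out)
  }
  raw <- colSums(concept_probs[sel, , drop = FALSE] * imp[sel])
  if (max(raw) <= 0) {
    warning("all raw concept scores are zero")
    return(out)
  }
  out[colnames(concept_probs) %||% concept_names()] <- 100 * raw / max(raw)
  out
}

#' Render an importance heatmap overlay
#'
#' Importance is mapped through a diverging blue-white-red color map (-1 =
#' blue, 0 = white/neutral, +1 = red) and alpha-blended over the slide image;
#' a vertical legend bar is appended on the right. Deterministic: rendering
#' twice gives bit-identical output.
#'
#' @param map Importance map from [occlusion_importance()].
#' @param slide_image h x w x 3 RGB array in \[0, 255\].
#' @param tile_px Tile side in pixels (the map's grid pitch).
#' @param alpha Blend weight of the color layer (default 0.4).
#' @param path Optional PNG output path.
#' @return The overlay array (values in \[0, 1\]), invisibly when written.
#' @export
render_heatmap <- function(map, slide_image, tile_px, alpha = 0.4,
                           path = NULL) {
  h <- dim(slide_image)[1]; w <- dim(slide_image)[2]
  if (max(map$grid_row + 1) * tile_px > h || max(map$grid_col + 1) * tile_px > w)
    stop("importance map does not align with the slide grid")
  pal <- colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(201)
  col_of <- function(v) { # v in [-1, 1]
    col2rgb(pal[round((pmax(pmin(v, 1), -1) + 1) * 100) + 1]) / 255
  }
  img <- slide_image / 255
  out <- img
  for (i in seq_len(nrow(map))) {
    rr <- map$grid_row[i] * tile_px + seq_len(tile_px)
    cc <- map$grid_col[i] * tile_px + seq_len(tile_px)
    rgb <- col_of(map$importance[i])
    for (ch in 1:3)
      out[rr, cc, ch] <- (1 - alpha) * img[rr, cc, ch] + alpha * rgb[ch]
  }
  # legend: vertical gradient +1 (top) to -1 (bottom)
  leg_w <- max(6L, round(w * 0.04))
  leg <- array(1, c(h, leg_w + 4L, 3))
  grad <- col_of(seq(1, -1, length.out = h))
  for (ch in 1:3) leg[, 4L + seq_len(leg_w), ch] <- matrix(grad[ch, ], h, leg_w)
  out <- abind3(out, leg)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

# column-bind two h x w x 3 arrays
abind3 <- function(a, b) {
  stopifnot(dim(a)[1] == dim(b)[1])
  out <- array(0, c(dim(a)[1], dim(a)[2] + dim(b)[2], 3))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}
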