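#' @title Microenvironment clustering of tile features
#' @description Tiles are grouped into K = 10 clusters by k-means, mirroring
#'   the ten region types of biological significance in colorectal pathology
#'   (lymphocyte, stroma, debris, mucus, muscle, tumor, adipose, background,
#'   normal, others). The clustering is fit globally on the training-set tiles
#'   and applied to every slide, so cluster identities are consistent across
#'   slides — a requirement of both the per-cluster transformer streams and
#'   the instance-loss cluster selection.
#' @name clustering
NULL

# k-means++ seeding (Arthur & Vassilvitskii); uses ambient RNG
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Fit the tile-feature cluster model
#'
#' Lloyd's algorithm with k-means++ initialization, `n_init` restarts
#' (best objective kept), fixed seed.
#'
#' @param bags List of `feature_bag`s (the training set).
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts (default 5).
#' @param iter_max Lloyd iteration cap (default 100).
#' @return A `cluster_model`: list with `k`, `centroids` (k x d), `fit_seed`,
#'   `training_slides`, `tot_withinss`.
#' @export
fit_clusters <- function(bags, k = 10, seed = 1, n_init = 5, iter_max = 100) {
  x <- do.call(rbind, lapply(bags, function(b) b$features))
  if (nrow(x) < k) stop("fewer tiles than clusters (k = ", k, ")")
  fit <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      init <- kmeanspp_init(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  structure(list(k = k, centroids = unname(fit$centers), fit_seed = seed,
                 training_slides = vapply(bags, function(b) b$slide_id,
                                          character(1)),
                 tot_withinss = fit$tot.withinss),
            class = "cluster_model")
}

#' Assign a bag's tiles to the nearest centroids
#'
#' Euclidean nearest-centroid assignment; ties are broken toward the lowest
#' cluster index. Cluster ids are 0-based (`0 .. k-1`). Empty clusters at
#' assignment time are permitted: downstream modules treat a slide's empty
#' cluster as an absent stream.
#'
#' @param bag A `feature_bag`.
#' @param model A `cluster_model` from [fit_clusters()].
#' @return A `cluster_assignment`: list with `slide_id`, `tile_ids`,
#'   `cluster_id` (integer per tile).
#' @export
assign_clusters <- function(bag, model) {
  if (ncol(bag$features) != ncol(model$centroids))
    stop("feature dimension does not match cluster centroids")
  x <- bag$features
  # squared distances via expansion; constant ||x||^2 omitted (rank-invariant)
  d <- -2 * x %*% t(model$centroids)
  d <- sweep(d, 2, rowSums(model$centroids^2), "+")
  cl <- max.col(-d, ties.method = "first") - 1L
  structure(list(slide_id = bag$slide_id, tile_ids = bag$tile_ids,
                 cluster_id = cl), class = "cluster_assignment")
}

#' Serialize / load a cluster model as JSON
#' @param model A `cluster_model`.
#' @param path JSON path.
#' @return The path (write) or the `cluster_model` (read).
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$centroids <- matrix(unlist(x$centroids), nrow = x$k, byrow = FALSE)
  structure(x, class = "cluster_model")
}
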