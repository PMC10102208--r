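#' @title Dual bag/instance objective and the censored Weibull likelihood
#' @description The slide classifier is trained with the sum of (i) a bag loss
#'   — cross-entropy with inverted class weights so minority classes are not
#'   drowned out — and (ii) an instance loss — a smoothed hinge (smooth SVM)
#'   on tiles of the attention-extreme clusters, pseudo-labeled positive (top
#'   three clusters) or negative (bottom three). The survival head is trained
#'   with the right-censored Weibull negative log-likelihood.
#' @name losses
NULL

#' Inverted class weights
#'
#' `w_c = N_total / (C * n_c)`: classes with fewer instances receive
#' proportionally larger weights, so the weighted per-class contributions are
#' balanced.
#'
#' @param class_counts Positive integer count per class (tiles or slides).
#' @return Numeric weight per class.
#' @export
inverted_class_weights <- function(class_counts) {
  if (any(class_counts < 1)) stop("every class must have a positive count")
  sum(class_counts) / (length(class_counts) * class_counts)
}

#' Weighted cross-entropy bag loss
#'
#' `-w_label * log(p_label)`; probabilities are clamped at `eps` with a
#' warning when the label's probability underflows to zero.
#'
#' @param class_probabilities Probability simplex vector.
#' @param label 1-based class index of the bag.
#' @param weights Per-class weights (default all 1).
#' @param eps Clamp for the log argument (default 1e-12).
#' @return Nonnegative scalar.
#' @export
bag_loss <- function(class_probabilities, label,
                     weights = rep(1, length(class_probabilities)),
                     eps = 1e-12) {
  p <- class_probabilities[label]
  if (p <= 0) {
    warning("label probability clamped at eps")
    p <- eps
  }
  -weights[label] * log(p)
}

#' Select attention-extreme clusters for instance supervision
#'
#' Ranks cluster attention weights and returns the `n_top` highest-attention
#' clusters (pseudo-label positive) and `n_bottom` lowest (pseudo-label
#' negative). Ties break toward the lower cluster index. When fewer than
#' `n_top + n_bottom` nonempty clusters exist, both counts are reduced
#' symmetrically (to `floor(m/2)` each) and a message is logged.
#'
#' @param cluster_attention Named (by cluster id) or plain numeric vector of
#'   attention weights over nonempty clusters.
#' @param n_top,n_bottom Cluster counts (defaults 3 and 3).
#' @return List with integer vectors `top` and `bottom` (cluster ids if names
#'   were supplied, else 0-based positions).
#' @export
select_extreme_clusters <- function(cluster_attention, n_top = 3,
                                    n_bottom = 3) {
  m <- length(cluster_attention)
  ids <- if (!is.null(names(cluster_attention)))
    as.integer(names(cluster_attention)) else seq_len(m) - 1L
  if (m < n_top + n_bottom) {
    n_top <- n_bottom <- m %/% 2L
    message("fewer nonempty clusters than requested; reduced to ",
            n_top, "/", n_bottom)
  }
  # one descending ranking, ties toward the lower cluster index; the top
  # pseudo-positives are its head, the bottom pseudo-negatives its tail
  rk <- order(-cluster_attention, ids)
  top <- ids[rk[seq_len(n_top)]]
  bottom <- ids[rk[m - n_bottom + seq_len(n_bottom)]]
  list(top = sort(top), bottom = sort(bottom))
}

# stable softplus
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Smooth-SVM (smoothed hinge) instance loss
#'
#' The smoothed hinge `l_tau(z) = tau * log(1 + exp((1 - z) / tau))`
#' converges pointwise to `max(0, 1 - z)` as `tau -> 0+` and upper-bounds it
#' for every `tau > 0`. The margin of a tile is
#' `z = s_target - max(s_other)` (one-vs-rest; the plain difference for binary
#' heads), negated for pseudo-negative tiles. Every tile in a selected cluster
#' inherits the cluster's pseudo-label.
#'
#' @param instance_scores Either a numeric vector of precomputed margins `z`,
#'   or an n x C matrix of per-tile class scores.
#' @param pseudo_labels Vector in \{1, -1\} per tile (ignored when margins are
#'   supplied; then margins are already signed).
#' @param tau Positive smoothing hyperparameter, tuned per task (default 1).
#' @param target_class 1-based index of the bag's class (matrix input only).
#' @return Nonnegative scalar: mean smoothed hinge over tiles.
#' @export
smooth_svm_instance_loss <- function(instance_scores, pseudo_labels = NULL,
                                     tau = 1, target_class = 2) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.matrix(instance_scores)) {
    s_t <- instance_scores[, target_class]
    s_o <- apply(instance_scores[, -target_class, drop = FALSE], 1, max)
    z <- (s_t - s_o) * pseudo_labels
  } else {
    z <- instance_scores
  }
  mean(tau * softplus((1 - z) / tau))
}

#' Total training objective
#'
#' The unweighted sum of the bag and instance losses; an optional multiplier
#' on the instance term exists but defaults to 1.
#'
#' @param bag Bag-loss scalar.
#' @param instance Instance-loss scalar.
#' @param instance_weight Multiplier on the instance term (default 1).
#' @return Scalar total loss.
#' @export
total_loss <- function(bag, instance, instance_weight = 1) {
  stopifnot(is.finite(bag), is.finite(instance))
  bag + instance_weight * instance
}

#' Right-censored Weibull negative log-likelihood
#'
#' For shape `kappa` and scale `lambda` (the `dweibull`/`rweibull`
#' parameterization): an observed event contributes the negative log-density
#' `-[log(kappa/lambda) + (kappa - 1) log(t/lambda) - (t/lambda)^kappa]`; a
#' right-censored record contributes the negative log-survival
#' `(t/lambda)^kappa`.
#'
#' @param lambda Scale parameter(s) > 0 (recycled).
#' @param kappa Shape parameter(s) > 0 (recycled).
#' @param time Observed or censoring time(s) > 0.
#' @param event 1 = event observed, 0 = right-censored.
#' @param eps Clamp for log arguments (default 1e-12).
#' @return Per-record NLL vector (sum it for a sample).
#' @export
weibull_negative_log_likelihood <- function(lambda, kappa, time, event,
                                            eps = 1e-12) {
  if (any(time <= 0)) stop("time must be > 0")
  stopifnot(all(lambda > 0), all(kappa > 0), all(event %in% c(0, 1)))
  ratio <- pmax(time / lambda, eps)
  haz_cum <- ratio^kappa
  log_dens <- log(pmax(kappa / lambda, eps)) +
    (kappa - 1) * log(ratio) - haz_cum
  ifelse(event == 1, -log_dens, haz_cum)
}
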