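#' @title Training orchestration: splits, optimizers, cross-validation
#' @description Slide-level leakage-free partitioning (all tiles of a slide
#'   stay in one partition), the SGD/momentum/weight-decay loop with cosine
#'   annealing for the classifier, and 5-fold cross-validation for the
#'   survival head.
#' @name training
NULL

#' Training configuration
#'
#' Defaults follow the production schedule: classification uses SGD with
#' learning rate 1e-3, momentum 0.9, weight decay 5e-4, batch size 1, 250
#' epochs and a cosine annealing scheduler; survival uses RMSprop-style
#' fitting with learning rate 1e-5 and 5 epochs. Tests use far smaller
#' epoch counts and a larger learning rate suited to the tiny architecture.
#'
#' @param task `"classification"` or `"survival"`.
#' @param optimizer `"sgd"` (momentum SGD, the classification default) or
#'   `"rmsprop"` (adaptive; the survival schedule, and the robust choice for
#'   the tiny test architecture whose class signal is small relative to the
#'   common embedding component).
#' @param split Train/validation/test fractions (default 0.6/0.2/0.2).
#' @param lr Learning rate (default 1e-3 classification, 1e-5 survival).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty (default 5e-4).
#' @param epochs Default 250 (classification) or 5 (survival).
#' @param batch_size Slides per step (the MIL setting uses 1).
#' @param cosine_annealing Use the cosine schedule (default TRUE).
#' @param seed Integer seed.
#' @param k_folds Survival cross-validation folds (default 5).
#' @param tau Smooth-SVM smoothing hyperparameter (default 1).
#' @param n_top,n_bottom Extreme-cluster counts for the instance loss.
#' @param instance_weight Multiplier on the instance loss (default 1).
#' @param eval_every Validation cadence in epochs (default 1).
#' @param clip_norm Global gradient-norm clip (default 1, standard for
#'   transformer training with batch size 1; `Inf` disables).
#' @return A `train_config` list.
#' @export
train_config <- function(task = c("classification", "survival"),
                         optimizer = c("sgd", "rmsprop"),
                         split = c(0.6, 0.2, 0.2),
                         lr = NULL, momentum = 0.9, weight_decay = 5e-4,
                         epochs = NULL, batch_size = 1,
                         cosine_annealing = TRUE, seed = 1, k_folds = 5,
                         tau = 1, n_top = 3, n_bottom = 3,
                         instance_weight = 1, eval_every = 1, clip_norm = 1) {
  task <- match.arg(task)
  optimizer <- match.arg(optimizer)
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3)
  lr <- lr %||% if (task == "classification") 1e-3 else 1e-5
  epochs <- epochs %||% if (task == "classification") 250 else 5
  stopifnot(epochs >= 1, lr > 0)
  structure(list(task = task, optimizer = optimizer, split = split,
                 lr = lr, momentum = momentum,
                 weight_decay = weight_decay, epochs = epochs,
                 batch_size = batch_size, cosine_annealing = cosine_annealing,
                 seed = seed, k_folds = k_folds, tau = tau, n_top = n_top,
                 n_bottom = n_bottom, instance_weight = instance_weight,
                 eval_every = eval_every, clip_norm = clip_norm),
            class = "train_config")
}

# cosine-annealed learning rate at 1-based epoch e
cosine_lr <- function(e, epochs, lr0, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (e - 1) / epochs))
}

#' Slide-level stratified cohort split
#'
#' Assigns every slide to train/val/test, stratified by label when present, so
#' that all of a slide's tiles share one partition (no information leaks).
#' Rounding: floor for validation and test within each stratum, remainder to
#' train. If a label class is absent from any partition the split is redrawn
#' (up to `max_retry` times, then an error).
#'
#' @param manifest Cohort manifest data.frame with `slide_id` and optionally
#'   `label`.
#' @param fractions Train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @param max_retry Redraw cap (default 20).
#' @return The manifest with its `partition` column filled
#'   (train/val/test).
#' @export
split_cohort <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1,
                         max_retry = 20) {
  stopifnot(nrow(manifest) >= 5, abs(sum(fractions) - 1) < 1e-8)
  has_label <- "label" %in% names(manifest) && !all(is.na(manifest$label))
  draw <- function(attempt) with_seed(seed + attempt, {
    part <- rep(NA_character_, nrow(manifest))
    strata <- if (has_label) split(seq_len(nrow(manifest)), manifest$label)
      else list(seq_len(nrow(manifest)))
    for (idx in strata) {
      idx <- sample(idx)
      n <- length(idx)
      n_val <- floor(n * fractions[2]); n_test <- floor(n * fractions[3])
      part[idx] <- c(rep("train", n - n_val - n_test),
                     rep("val", n_val), rep("test", n_test))
    }
    part
  })
  for (attempt in 0:max_retry) {
    part <- draw(attempt)
    if (!has_label) break
    ok <- all(vapply(c("train", "val", "test"), function(p) {
      length(unique(manifest$label[part == p])) ==
        length(unique(manifest$label))
    }, logical(1)))
    if (ok) break
    if (attempt == max_retry)
      stop("could not produce a split with every class in every partition")
  }
  manifest$partition <- part
  manifest
}

# Build the total-loss node on a forward pass's tape.
# Selection of extreme clusters and of the runner-up class is discrete and
# treated as constant during backpropagation (standard subgradient practice).
mil_loss_nodes <- function(fw, label, class_weights, config, tc) {
  tape <- fw$nodes$tape
  n_classes <- config$n_classes
  onehot <- matrix(0, 1, n_classes); onehot[1, label] <- 1
  bagn <- ad_scale(tape,
    ad_sum(tape, ad_mul_const(tape, ad_log(tape, fw$nodes$prob), onehot)),
    -class_weights[label])
  sel <- select_extreme_clusters(fw$cluster_attention, tc$n_top, tc$n_bottom)
  ones <- ad_input(tape, matrix(1, n_classes, 1))
  pieces <- list()
  for (ci in seq_along(fw$clusters)) {
    cid <- fw$clusters[ci]
    sign <- if (cid %in% sel$top) 1 else if (cid %in% sel$bottom) -1 else next
    sn <- fw$nodes$instance[[ci]] # n_c x C logits
    sv <- sn$value
    umat <- matrix(0, nrow(sv), n_classes)
    umat[, label] <- 1
    others <- setdiff(seq_len(n_classes), label)
    run_up <- others[max.col(sv[, others, drop = FALSE], ties.method = "first")]
    umat[cbind(seq_len(nrow(sv)), run_up)] <- -1
    zn <- ad_matmul(tape, ad_mul_const(tape, sn, umat * sign), ones)
    pieces[[length(pieces) + 1]] <-
      ad_scale(tape, ad_softplus(tape,
        ad_scale(tape, ad_shift(tape, ad_scale(tape, zn, -1), 1), 1 / tc$tau)),
        tc$tau)
  }
  instn <- if (length(pieces) == 0) ad_input(tape, matrix(0, 1, 1))
    else ad_mean(tape, ad_rbind(tape, pieces))
  total <- ad_add(tape, bagn, ad_scale(tape, instn, tc$instance_weight))
  list(total = total, bag = bagn$value[1, 1], instance = instn$value[1, 1])
}

# rescale a gradient structure so its global L2 norm is at most clip_norm
clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  sq <- 0
  walk <- function(g) {
    if (is.matrix(g)) sq <<- sq + sum(g^2) else lapply(g, walk)
    invisible(NULL)
  }
  walk(grads)
  nrm <- sqrt(sq)
  if (nrm <= clip_norm) return(grads)
  scale_by <- clip_norm / nrm
  rescale <- function(g) if (is.matrix(g)) g * scale_by else lapply(g, rescale)
  rescale(grads)
}

# one SGD step with momentum and weight decay; returns list(params, velocity)
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  velocity <- param_map2(velocity, param_map2(grads, params, function(g, p)
    g + weight_decay * p), function(v, g) momentum * v + g)
  params <- param_map2(params, velocity, function(p, v) p - lr * v)
  list(params = params, velocity = velocity)
}

# one RMSprop step (running mean-square cache in `velocity`)
rmsprop_step <- function(params, grads, velocity, lr, weight_decay,
                         alpha = 0.99, eps = 1e-8) {
  g <- param_map2(grads, params, function(gr, p) gr + weight_decay * p)
  velocity <- param_map2(velocity, g, function(v, gr)
    alpha * v + (1 - alpha) * gr^2)
  params <- param_map2(params, param_map2(g, velocity, function(gr, v)
    gr / (sqrt(v) + eps)), function(p, u) p - lr * u)
  list(params = params, velocity = velocity)
}

#' Train the slide classifier
#'
#' SGD with momentum, weight decay, batch size 1 and cosine annealing on the
#' dual bag + instance objective. Class weights are inverted-count weights
#' over the per-class tile totals. The checkpoint with the best validation
#' AUROC (score of the positive/last class) is returned. Deterministic given
#' the seed.
#'
#' @param bags Named-by-nothing list of training `feature_bag`s.
#' @param labels Integer class labels (1-based) aligned to `bags`.
#' @param assignments List of `cluster_assignment`s aligned to `bags`.
#' @param model An initialized `mil_model`.
#' @param tc A [train_config()].
#' @param val_bags,val_labels,val_assignments Optional validation set; without
#'   one the final-epoch model is returned.
#' @return List with `model` (best checkpoint), `final_model`, `log`
#'   (per-step data.frame: epoch, step, bag_loss, instance_loss, total, lr),
#'   `best_epoch`, `best_val_auroc`, `val_history`.
#' @export
train_classifier <- function(bags, labels, assignments, model, tc,
                             val_bags = NULL, val_labels = NULL,
                             val_assignments = NULL) {
  config <- model$config
  tile_counts <- vapply(split(seq_along(bags), labels), function(ix)
    sum(vapply(bags[ix], function(b) nrow(b$features), numeric(1))),
    numeric(1))
  counts <- numeric(config$n_classes)
  counts[as.integer(names(tile_counts))] <- tile_counts
  if (any(counts < 1)) stop("a class is absent from the training data")
  w <- inverted_class_weights(counts)
  params <- model$params
  velocity <- param_map2(params, params, function(p, q) p * 0)
  log_rows <- vector("list", tc$epochs * length(bags))
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  val_hist <- data.frame(epoch = integer(), val_auroc = numeric())
  li <- 0L
  with_seed(tc$seed, {
    for (e in seq_len(tc$epochs)) {
      lr <- if (tc$cosine_annealing) cosine_lr(e, tc$epochs, tc$lr) else tc$lr
      ord <- sample(seq_along(bags))
      for (si in seq_along(ord)) {
        i <- ord[si]
        m <- model; m$params <- params
        fw <- mil_forward(m, bags[[i]], assignments[[i]], train = TRUE)
        ln <- mil_loss_nodes(fw, labels[i], w, config, tc)
        if (!is.finite(ln$total$value[1, 1]))
          stop("training diverged: non-finite loss at epoch ", e)
        ad_backward(fw$nodes$tape, ln$total)
        grads <- clip_gradients(param_grads(fw$nodes$params), tc$clip_norm)
        upd <- if (identical(tc$optimizer, "rmsprop"))
          rmsprop_step(params, grads, velocity, lr, tc$weight_decay)
        else sgd_step(params, grads, velocity, lr, tc$momentum,
                      tc$weight_decay)
        params <- upd$params; velocity <- upd$velocity
        li <- li + 1L
        log_rows[[li]] <- data.frame(epoch = e, step = si,
                                     bag_loss = ln$bag,
                                     instance_loss = ln$instance,
                                     total = ln$total$value[1, 1], lr = lr)
      }
      if (!is.null(val_bags) && (e %% tc$eval_every == 0 || e == tc$epochs)) {
        m <- model; m$params <- params
        sc <- vapply(seq_along(val_bags), function(j)
          mil_forward(m, val_bags[[j]], val_assignments[[j]])
            $class_probabilities[config$n_classes], numeric(1))
        va <- auroc(sc, as.integer(val_labels == config$n_classes))
        val_hist <- rbind(val_hist, data.frame(epoch = e, val_auroc = va))
        if (va > best$auroc) best <- list(auroc = va, params = params,
                                          epoch = e)
      }
    }
  })
  final <- model; final$params <- params
  best_model <- model
  best_model$params <- if (is.null(val_bags)) params else best$params
  list(model = best_model, final_model = final,
       log = do.call(rbind, log_rows[seq_len(li)]),
       best_epoch = if (is.null(val_bags)) tc$epochs else best$epoch,
       best_val_auroc = if (is.null(val_bags)) NA_real_ else best$auroc,
       val_history = val_hist)
}

#' Slide-level k-fold cross-validation of the survival head
#'
#' Folds partition slides exactly once. Per fold, a linear Weibull head is fit
#' on the training folds, the held-out fold is scored (risk = negative
#' survival index), and the held-out c-index and log-rank test between risk
#' groups — thresholded at the TRAINING folds' median survival index — are
#' recorded. A fold whose training part has no events is merged into its
#' neighbor.
#'
#' @param manifest Cohort manifest with `time`, `event` and covariate columns.
#' @param k Number of folds (default 5).
#' @param covar_cols Covariate column names (default: all `x<digit>` columns).
#' @param seed Integer seed for the fold draw.
#' @return List with `folds` (per-fold data.frame: fold, n, c_index,
#'   logrank_p), `mean_c_index`, `sd_c_index`, and `pooled` (per-slide
#'   predictions with risk groups, pooled over folds).
#' @export
cross_validate_survival <- function(manifest, k = 5, covar_cols = NULL,
                                    seed = 1) {
  stopifnot(all(c("time", "event") %in% names(manifest)))
  covar_cols <- covar_cols %||% grep("^x[0-9]+$", names(manifest),
                                     value = TRUE)
  n <- nrow(manifest)
  if (n < k) stop("fewer slides with survival records than folds")
  x <- as.matrix(manifest[, covar_cols, drop = FALSE])
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  # merge folds whose training complement would carry no events
  for (f in seq_len(k)) {
    if (sum(manifest$event[fold != f]) == 0) {
      fold[fold == f] <- if (f == k) f - 1L else f + 1L
      message("fold ", f, " merged into neighbor (no training events)")
    }
  }
  rows <- list(); pooled <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- fold == f
    head_fit <- fit_weibull_head(x[tr, , drop = FALSE], manifest$time[tr],
                                 manifest$event[tr])
    idx_tr <- survival_index(predict_weibull(x[tr, , drop = FALSE], head_fit))
    thr <- median(idx_tr)
    pr_te <- predict_weibull(x[te, , drop = FALSE], head_fit)
    idx_te <- survival_index(pr_te)
    ci <- concordance_index(manifest$time[te], manifest$event[te], -idx_te)
    grp <- stratify(idx_te, threshold = thr)$risk_group
    lr_p <- tryCatch({
      a <- grp == "shorter-term"
      logrank_test(manifest$time[te][a], manifest$event[te][a],
                   manifest$time[te][!a], manifest$event[te][!a])$p_value
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(fold = f, n = sum(te),
                                           c_index = ci, logrank_p = lr_p)
    pooled[[length(pooled) + 1]] <-
      data.frame(slide_id = manifest$slide_id[te], fold = f,
                 lambda = pr_te$lambda, kappa = pr_te$kappa,
                 survival_index = idx_te, risk_group = as.character(grp))
  }
  folds <- do.call(rbind, rows)
  list(folds = folds, mean_c_index = mean(folds$c_index),
       sd_c_index = sd(folds$c_index), pooled = do.call(rbind, pooled))
}
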