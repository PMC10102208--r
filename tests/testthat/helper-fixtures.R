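# Shared fixtures (memoised: built once per test run) and independent
# brute-force oracles used by the metric and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Full planted-cohort pipeline: slides -> tiles -> features -> scaling ->
# clusters -> trained tiny MIL classifier. The study conditions of the
# planted-signal checks (60 slides, 6x6 grid of 32 px tiles, tumor presence
# label), trained for 50 epochs at lr 0.005.
planted_pipeline <- function() memo("planted", function() {
  co <- simulate_planted_cohort(n_slides = 60, seed = 11)
  cfg <- preprocess_config(tile_size_px = 32)
  bags <- lapply(seq_along(co$slides), function(s)
    extract_features(tile_slide(co$slides[[s]]$image, cfg,
                                co$manifest$slide_id[s]),
                     backbone_spec("tiny")))
  man <- split_cohort(co$manifest, seed = 5)
  tr <- which(man$partition == "train")
  va <- which(man$partition == "val")
  te <- which(man$partition == "test")
  scaler <- fit_feature_scaler(bags[tr])
  bags <- lapply(bags, scale_bag, scaler = scaler)
  cmodel <- fit_clusters(bags[tr], k = 10, seed = 3)
  asg <- lapply(bags, assign_clusters, model = cmodel)
  labels <- man$label + 1L
  model <- mil_model_init(mil_config_tiny(), input_dim = 16, seed = 7)
  tc <- train_config("classification", optimizer = "rmsprop", lr = 0.001,
                     epochs = 50, seed = 9, eval_every = 1)
  res <- suppressMessages(
    train_classifier(bags[tr], labels[tr], asg[tr], model, tc,
                     bags[va], labels[va], asg[va]))
  # tumor ground-truth flag per bag row
  tumor_flags <- lapply(seq_along(bags), function(s) {
    rc <- moma:::parse_tile_ids(bags[[s]]$tile_ids)
    co$tumor_tiles[[s]][rc$row * co$grid + rc$col + 1]
  })
  list(cohort = co, man = man, bags = bags, assignments = asg,
       cluster_model = cmodel, fit = res, model = res$model,
       tr = tr, va = va, te = te, tumor_flags = tumor_flags)
})

# small untrained model for structural tests
tiny_model <- function(input_dim = 8, seed = 2)
  mil_model_init(mil_config_tiny(), input_dim = input_dim, seed = seed)

## --- independent brute-force metric oracles --------------------------------

oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

oracle_cindex <- function(time, event, risk) {
  conc <- 0; tot <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    tot <- tot + 1
    if (risk[i] > risk[j]) conc <- conc + 1
    else if (risk[i] == risk[j]) conc <- conc + 0.5
  }
  if (tot == 0) stop("no comparable pairs")
  conc / tot
}

oracle_km <- function(time, event) {
  s <- 1
  out <- NULL
  for (tt in sort(unique(time[event == 1]))) {
    n_r <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_r)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# log-rank via explicit hypergeometric accumulation
oracle_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(c(0, 1), c(length(ta), length(tb)))
  u <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & grp == 0)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 0)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- u^2 / v
  c(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}
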