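#' @title Task metrics: AUROC, concordance, Kaplan-Meier, log-rank
#' @name evaluation
NULL

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs in which the positive sample scores
#' higher; tied scores count 1/2.
#'
#' @param scores Numeric score per sample.
#' @param labels 0/1 label per sample (both classes must be present).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  cmp <- outer(pos, neg, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

#' Harrell's concordance index
#'
#' Over comparable pairs — the earlier time must be an observed event — the
#' fraction where the earlier-failing sample carries the higher risk score;
#' risk ties count 1/2. Pairs censored before the other's event are not
#' comparable.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param risk_scores Predicted risk (higher = earlier expected failure).
#' @return c-index in \[0, 1\].
#' @export
concordance_index <- function(time, event, risk_scores) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk_scores) == n)
  conc <- 0; total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # order the pair so `a` fails/censors first
      if (time[i] < time[j]) { a <- i; b <- j }
      else if (time[j] < time[i]) { a <- j; b <- i }
      else {
        # tied times: comparable only when exactly one is an event
        if (event[i] == event[j]) next
        a <- if (event[i] == 1) i else j; b <- if (event[i] == 1) j else i
        total <- total + 1
        if (risk_scores[a] > risk_scores[b]) conc <- conc + 1
        else if (risk_scores[a] == risk_scores[b]) conc <- conc + 0.5
        next
      }
      if (event[a] != 1) next # earlier sample censored: not comparable
      total <- total + 1
      if (risk_scores[a] > risk_scores[b]) conc <- conc + 1
      else if (risk_scores[a] == risk_scores[b]) conc <- conc + 0.5
    }
  }
  if (total == 0) stop("no comparable pairs")
  conc / total
}

#' Kaplan-Meier product-limit curve
#'
#' Right-continuous non-increasing step function with `S(0) = 1` and steps at
#' event times only.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`
#'   (one row per distinct event time; empty when no events).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(event) == length(time))
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = numeric(0),
                    n_event = numeric(0), surv = numeric(0))
  for (tt in ev_times) {
    n_risk <- sum(time >= tt)
    n_event <- sum(time == tt & event == 1)
    s <- s * (1 - n_event / n_risk)
    out <- rbind(out, data.frame(time = tt, n_risk = n_risk,
                                 n_event = n_event, surv = s))
  }
  out
}

# survival probability of a km curve at time t (right-continuous)
km_surv_at <- function(km, t) {
  if (nrow(km) == 0) return(rep(1, length(t)))
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i) == 0) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' At each distinct event time, the observed events in group A are compared
#' with their hypergeometric expectation under the null of identical hazards;
#' the statistic `(O - E)^2 / V` is referred to a chi-square distribution with
#' one degree of freedom (two-sided convention).
#'
#' @param time_a,event_a Times and event indicators of group A.
#' @param time_b,event_b Times and event indicators of group B.
#' @return List with `statistic`, `p_value`, `observed` (per group),
#'   `expected` (per group).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0, 1), c(length(time_a), length(time_b)))
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0) stop("no events: log-rank variance is zero")
  o_minus_e <- 0; v <- 0; obs_a <- 0; exp_a <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0)
    d <- sum(time == tt & event == 1)
    d_a <- sum(time == tt & event == 1 & grp == 0)
    e_a <- d * n_a / n
    obs_a <- obs_a + d_a
    exp_a <- exp_a + e_a
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (v <= 0) stop("log-rank variance is zero")
  stat <- o_minus_e^2 / v
  total_d <- sum(event)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(a = obs_a, b = total_d - obs_a),
       expected = c(a = exp_a, b = total_d - exp_a))
}
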