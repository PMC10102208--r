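#' @title Weibull survival head and risk stratification
#' @description A linear head maps an embedding (or covariate vector) to the
#'   two Weibull parameters through domain-guaranteeing activations —
#'   `lambda = exp(a)` and `kappa = softplus(b)` — and is trained by the
#'   right-censored Weibull negative log-likelihood. The predicted median,
#'   `lambda * log(2)^(1/kappa)`, serves as the survival index; cohorts are
#'   split at the training-fold median index into predicted longer-term and
#'   shorter-term survival groups.
#' @name survival_head
NULL

#' Map head outputs to Weibull parameters
#'
#' Given a linear head `(w_a, c_a, w_b, c_b)` and input `x`:
#' `a = x . w_a + c_a`, `b = x . w_b + c_b`, then `lambda = exp(a)` and
#' `kappa = softplus(b) = log(1 + exp(b))`, both strictly positive by
#' construction.
#'
#' @param x Numeric matrix (n x p) or vector of embeddings/covariates.
#' @param head A `weibull_head` (list with `w_a`, `c_a`, `w_b`, `c_b`).
#' @return data.frame with columns `lambda` and `kappa`.
#' @export
predict_weibull <- function(x, head) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(head$w_a)) stop("embedding dimension mismatch")
  a <- as.vector(x %*% head$w_a) + head$c_a
  b <- as.vector(x %*% head$w_b) + head$c_b
  data.frame(lambda = exp(a), kappa = softplus(b))
}

#' Fit a linear Weibull head by maximum likelihood
#'
#' Minimizes the summed [weibull_negative_log_likelihood()] over the head's
#' parameters with BFGS, starting from zero weights.
#'
#' @param x n x p matrix of embeddings or covariates.
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param maxit Optimizer iteration cap (default 500).
#' @return A `weibull_head`: list with `w_a`, `c_a`, `w_b`, `c_b`,
#'   `nll` (final summed NLL) and `converged`.
#' @export
fit_weibull_head <- function(x, time, event, maxit = 500) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  p <- ncol(x)
  unpack <- function(par) list(w_a = par[seq_len(p)], c_a = par[p + 1],
                               w_b = par[p + 1 + seq_len(p)],
                               c_b = par[2 * p + 2])
  nll <- function(par) {
    h <- unpack(par)
    # clamped activations: the optimizer may probe extreme linear outputs
    a <- pmin(pmax(as.vector(x %*% h$w_a) + h$c_a, -500), 500)
    b <- as.vector(x %*% h$w_b) + h$c_b
    lambda <- exp(a)
    kappa <- pmax(softplus(b), 1e-10)
    s <- sum(weibull_negative_log_likelihood(lambda, kappa, time, event))
    if (!is.finite(s)) 1e10 else s
  }
  # start at log(mean time) intercept, kappa ~ 1 (softplus^-1(1) = log(e - 1))
  par0 <- c(rep(0, p), log(mean(time)), rep(0, p), log(exp(1) - 1))
  fit <- optim(par0, nll, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  out <- unpack(fit$par)
  out$nll <- fit$value
  out$converged <- fit$convergence == 0
  class(out) <- "weibull_head"
  out
}

#' Predicted survival index
#'
#' The median of the predicted Weibull distribution,
#' `lambda * log(2)^(1/kappa)` (default), or the mean
#' `lambda * gamma(1 + 1/kappa)` behind the `statistic` switch. Monotone
#' increasing in `lambda`.
#'
#' @param params data.frame or list with `lambda`, `kappa`.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Positive survival index (vectorized).
#' @export
survival_index <- function(params, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (statistic == "median") params$lambda * log(2)^(1 / params$kappa)
  else params$lambda * gamma(1 + 1 / params$kappa)
}

#' Stratify predictions into prognosis groups
#'
#' Indices above the threshold are `"longer-term"`, at or below it
#' `"shorter-term"`. With `threshold = "median-of-cohort"` the threshold is
#' the median of the supplied indices (ties fall to shorter-term). To avoid
#' test-set leakage, compute the threshold on a training fold and pass it
#' frozen to validation/test cohorts.
#'
#' @param survival_indices Numeric vector of predicted survival indices
#'   (length >= 2).
#' @param threshold Numeric threshold, or `"median-of-cohort"` (default).
#' @return List with `risk_group` (factor, levels shorter-term/longer-term)
#'   and `threshold`.
#' @export
stratify <- function(survival_indices, threshold = "median-of-cohort") {
  stopifnot(length(survival_indices) >= 2)
  if (identical(threshold, "median-of-cohort"))
    threshold <- median(survival_indices)
  if (length(unique(survival_indices)) == 1)
    warning("all survival indices identical; everyone in shorter-term group")
  grp <- ifelse(survival_indices > threshold, "longer-term", "shorter-term")
  list(risk_group = factor(grp, levels = c("shorter-term", "longer-term")),
       threshold = threshold)
}

#' Survival predictions for a cohort
#'
#' Convenience wrapper: head outputs, survival index and risk group in one
#' data.frame (the CSV written by the CLI).
#'
#' @param x n x p matrix of embeddings or covariates.
#' @param head A `weibull_head`.
#' @param slide_ids Identifiers (default row numbers).
#' @param threshold Passed to [stratify()].
#' @return data.frame (slide_id, lambda, kappa, survival_index, risk_group).
#' @export
predict_survival <- function(x, head, slide_ids = NULL,
                             threshold = "median-of-cohort") {
  pr <- predict_weibull(x, head)
  idx <- survival_index(pr)
  st <- stratify(idx, threshold)
  data.frame(slide_id = slide_ids %||% seq_along(idx),
             lambda = pr$lambda, kappa = pr$kappa, survival_index = idx,
             risk_group = as.character(st$risk_group))
}
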