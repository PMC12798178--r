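# Bayesian leave-one-out predictive evaluation via Pareto-smoothed
# importance sampling (PSIS), with an exact-refit fallback for observations
# whose importance weights are unreliable.

# Fit a generalized Pareto distribution to tail exceedances (Zhang &
# Stephens 2009 profile-posterior method). Returns shape k and scale sigma.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  prior_b <- 3
  q1 <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_b * q1)
  k_of <- function(th) -mean(log1p(-th * x))
  l_theta <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, 0)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_theta - l_theta[j])), 0)
  theta_hat <- sum(theta * w)
  k_zs <- k_of(theta_hat)
  # Zhang-Stephens' shape is the negative of the usual GPD xi convention
  list(k = -k_zs, sigma = k_zs / theta_hat)
}

# GPD quantile function (location 0).
.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns the smoothed
# log weights (unnormalized) and the tail shape diagnostic k.
.psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lr <- log_ratios - max(log_ratios)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5L || length(unique(lr)) < 5L) {
    return(list(log_w = lr, k = NA_real_))
  }
  ord <- order(lr)
  cutoff_idx <- S - tail_len
  cutoff <- lr[ord[cutoff_idx]]
  tail_ids <- ord[(cutoff_idx + 1L):S]
  exc <- exp(lr[tail_ids]) - exp(cutoff)
  if (all(exc <= 0) || length(unique(exc)) < 5L) {
    return(list(log_w = lr, k = NA_real_))
  }
  fit <- .gpd_fit(exc[exc > 0])
  # replace the tail by expected order statistics of the fitted GPD
  qq <- (rank(lr[tail_ids], ties.method = "first") - 0.5) / tail_len
  smoothed <- log(exp(cutoff) + .gpd_quantile(qq, fit$k, fit$sigma))
  smoothed <- pmin(smoothed, 0) # truncate at the max raw (shifted) weight
  lw <- lr
  lw[tail_ids] <- smoothed
  list(log_w = lw, k = fit$k)
}

#' PSIS leave-one-out predictive probabilities
#'
#' Approximates, for each modeled observation, the posterior predictive
#' probability of steady work that a model refit *without* that observation
#' would assign to it. Importance ratios `1 / p(y_i | theta_s)` are
#' stabilized by generalized-Pareto smoothing of their largest values; the
#' per-observation Pareto shape `k` diagnoses reliability (k > `k_threshold`
#' is conventionally unreliable). Such observations can optionally be
#' re-evaluated by an exact refit with the observation held out.
#'
#' @param fit An `sw_fit` (any family; uses the pointwise `log_lik` matrix).
#' @param k_threshold Pareto-k above which an observation is flagged
#'   (default 0.7).
#' @param refit Function taking the index of the held-out observation and
#'   returning its exact LOO predictive probability, or `NULL` (default) to
#'   skip exact refits and keep the PSIS estimate.
#' @return An object of class `sw_loo`: data frame with per-observation
#'   `prob` (LOO predictive probability of steady work), `pareto_k`,
#'   `refit` flag, plus attributes `y` and `elpd` (sum of LOO log
#'   predictive densities).
#' @export
psis_loo <- function(fit, k_threshold = 0.7, refit = NULL) {
  if (is.null(fit$log_lik)) stop("fit has no pointwise log-likelihood matrix",
                                 call. = FALSE)
  ll <- fit$log_lik
  S <- nrow(ll); n <- ncol(ll)
  if (S < 2L || all(apply(ll, 2, function(x) max(x) - min(x)) < 1e-12)) {
    warning("posterior draws are (near) identical; importance weights are degenerate",
            call. = FALSE)
  }
  y <- fit$y
  prob <- numeric(n); kdiag <- numeric(n); elpd_i <- numeric(n)
  did_refit <- logical(n)
  for (i in seq_len(n)) {
    p_i <- if (y[i] == 1L) exp(ll[, i]) else 1 - exp(ll[, i])
    if (S == 1L) {
      prob[i] <- p_i; kdiag[i] <- NA_real_; elpd_i[i] <- ll[1L, i]
      next
    }
    sm <- .psis_smooth(-ll[, i])
    w <- exp(sm$log_w - max(sm$log_w))
    w <- w / sum(w)
    prob[i] <- sum(w * p_i)
    kdiag[i] <- sm$k
    elpd_i[i] <- log(sum(w * exp(ll[, i])))
    if (!is.null(refit) && is.finite(sm$k) && sm$k > k_threshold) {
      prob[i] <- refit(i)
      elpd_i[i] <- log(ifelse(y[i] == 1L, prob[i], 1 - prob[i]))
      did_refit[i] <- TRUE
    }
  }
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  out <- data.frame(prob = prob, pareto_k = kdiag, refit = did_refit)
  attr(out, "y") <- y
  attr(out, "elpd") <- sum(elpd_i)
  attr(out, "family") <- fit$family
  attr(out, "predictor_set") <- fit$predictor_set
  class(out) <- c("sw_loo", "data.frame")
  out
}

#' @export
print.sw_loo <- function(x, ...) {
  cat("<sw_loo> ", nrow(x), " observations; elpd = ",
      round(attr(x, "elpd"), 1), "\n", sep = "")
  bad <- sum(x$pareto_k > 0.7, na.rm = TRUE)
  cat("  pareto-k > 0.7: ", bad, " (", sum(x$refit), " refit exactly)\n", sep = "")
  invisible(x)
}
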