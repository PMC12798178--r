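# Adaptive random-walk Metropolis sampler for validation-scale posteriors
# (small n, normal priors). Used where genuinely calibrated posterior draws
# matter more than speed: exact-refit leave-one-out checks and small-sample
# diagnostics.

#' Adaptive random-walk Metropolis sampling of a log density
#'
#' Gaussian proposals whose covariance adapts to the accumulated sample
#' covariance during warmup (scaled by `2.38^2/d`), with a diagonal jitter
#' floor. Adaptation stops after warmup, so the retained chain is a valid
#' Markov chain.
#'
#' @param logp Function of a parameter vector returning the joint log
#'   density.
#' @param init Initial parameter vector.
#' @param draws Retained draws after warmup.
#' @param warmup Warmup iterations (adaptation window).
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer seed.
#' @return List with `draws` (matrix `draws x d`) and `accept_rate`.
#' @keywords internal
rw_metropolis <- function(logp, init, draws = 2000L, warmup = 1000L,
                          thin = 2L, seed = 1L) {
  set.seed(seed)
  d <- length(init)
  x <- init
  lp <- logp(x)
  if (!is.finite(lp)) stop("non-finite log density at init", call. = FALSE)
  total <- warmup + draws * thin
  out <- matrix(NA_real_, draws, d)
  scale <- 2.38 / sqrt(d)
  chol_S <- diag(0.1, d)
  acc <- 0L
  hist <- matrix(NA_real_, warmup, d)
  for (it in seq_len(total)) {
    prop <- x + scale * drop(stats::rnorm(d) %*% chol_S)
    lpp <- logp(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      x <- prop; lp <- lpp; acc <- acc + 1L
    }
    if (it <= warmup) {
      hist[it, ] <- x
      if (it %% 200L == 0L && it >= 400L) {
        S <- stats::cov(hist[seq_len(it), , drop = FALSE]) + diag(1e-6, d)
        chol_S <- chol(S)
        # nudge the global scale toward ~23% acceptance
        rate <- acc / it
        scale <- scale * exp(0.5 * (rate - 0.234))
      }
    } else if ((it - warmup) %% thin == 0L) {
      out[(it - warmup) %/% thin, ] <- x
    }
  }
  list(draws = out, accept_rate = acc / total)
}
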