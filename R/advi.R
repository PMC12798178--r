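# Mean-field Gaussian variational inference with reparameterization
# gradients (ADVI-style) and Adam updates. Models supply a joint
# log-density-and-gradient callback over an unconstrained parameter vector;
# constrained parameters (scales etc.) are handled inside the callbacks via
# log transforms with their Jacobians folded into the log joint.

# Adam optimizer state update (vectorized over parameters).
.adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$x <- state$x + lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Mean-field variational fit of an arbitrary differentiable log joint
#'
#' Maximizes the ELBO of a diagonal-Gaussian approximation
#' `q(theta) = N(mu, diag(sigma^2))` by stochastic gradient ascent with the
#' reparameterization trick (`theta = mu + sigma * eps`), analytic entropy,
#' and Adam updates with a `1/sqrt(t)` learning-rate decay.
#'
#' @param logp_grad Function taking a `d x S` matrix of parameter draws and
#'   returning `list(logp = <length-S>, grad = <d x S matrix>)` of the joint
#'   log density and its gradient per draw.
#' @param d Parameter dimension.
#' @param iters Number of optimization steps.
#' @param mc_samples Monte Carlo samples per step.
#' @param lr Base Adam learning rate.
#' @param init_mu,init_log_sigma Initial variational parameters (scalars are
#'   recycled).
#' @param seed Integer seed; fits are reproducible.
#' @param monitor_every Record the running ELBO estimate every this many
#'   steps.
#' @return List with `mu`, `sigma`, `elbo_trace`, `converged` (relative
#'   change of the smoothed ELBO over the last two monitoring windows below
#'   1%), and `iters`.
#' @keywords internal
advi <- function(logp_grad, d, iters = 2000L, mc_samples = 2L, lr = 0.02,
                 init_mu = 0, init_log_sigma = -2.3, seed = 1L,
                 monitor_every = 50L) {
  set.seed(seed)
  mu <- rep_len(init_mu, d)
  ls <- rep_len(init_log_sigma, d)
  st_mu <- list(x = mu, m = numeric(d), v = numeric(d), t = 0L)
  st_ls <- list(x = ls, m = numeric(d), v = numeric(d), t = 0L)
  elbo_acc <- 0
  trace <- numeric(0)
  for (it in seq_len(iters)) {
    sigma <- exp(st_ls$x)
    eps <- matrix(stats::rnorm(d * mc_samples), d, mc_samples)
    theta <- st_mu$x + sigma * eps
    ev <- logp_grad(theta)
    g <- ev$grad
    if (!all(is.finite(g))) {
      g[!is.finite(g)] <- 0
    }
    gmu <- rowMeans(g)
    gls <- rowMeans(g * eps) * sigma + 1 # + entropy gradient
    lr_t <- lr / sqrt(it / 100 + 1)
    st_mu <- .adam_step(st_mu, gmu, lr_t)
    st_ls <- .adam_step(st_ls, pmin(pmax(gls, -1e4), 1e4), lr_t)
    st_ls$x <- pmin(st_ls$x, 2) # guard against runaway variational scales
    elbo_acc <- elbo_acc + mean(ev$logp) + sum(st_ls$x)
    if (it %% monitor_every == 0L) {
      trace <- c(trace, elbo_acc / monitor_every)
      elbo_acc <- 0
    }
  }
  nw <- length(trace)
  converged <- if (nw >= 4L) {
    recent <- mean(trace[(nw - 1L):nw])
    prev <- mean(trace[(nw - 3L):(nw - 2L)])
    is.finite(recent) && abs(recent - prev) <= 0.01 * (abs(prev) + 1)
  } else NA
  list(mu = st_mu$x, sigma = exp(st_ls$x), elbo_trace = trace,
       converged = converged, iters = iters)
}

# Draw S samples from a fitted mean-field approximation: d x S matrix.
.advi_draws <- function(fit, S, seed) {
  set.seed(seed)
  fit$mu + fit$sigma * matrix(stats::rnorm(length(fit$mu) * S), length(fit$mu), S)
}
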