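# Bayesian neural network comparator: single tanh hidden layer (width 12),
# standard-normal weight priors, mean-field variational inference. Missing
# inputs are zero-filled after standardization (i.e. set to the column mean)
# with missing-indicator columns appended -- a pragmatic stand-in for the
# linear model's full latent marginalization, documented as such.

#' Network architecture for the Bayesian neural network
#'
#' @param hidden Hidden layer width (default 12).
#' @param activation Hidden activation; `"tanh"`.
#' @param weight_prior_sd SD of the Normal prior on all weights and biases.
#' @return An object of class `sw_bnn_arch`.
#' @export
bnn_architecture <- function(hidden = 12L, activation = "tanh",
                             weight_prior_sd = 1) {
  if (hidden < 1L) stop("hidden width must be positive", call. = FALSE)
  if (!identical(activation, "tanh")) {
    stop("only the tanh activation is implemented", call. = FALSE)
  }
  if (weight_prior_sd <= 0) stop("weight_prior_sd must be positive", call. = FALSE)
  structure(list(hidden = as.integer(hidden), activation = activation,
                 weight_prior_sd = weight_prior_sd), class = "sw_bnn_arch")
}

# Augment the design matrix for the network: zero-fill missing cells and
# append one missing-indicator column per column that has any missing cell.
.bnn_inputs <- function(design) {
  X0 <- design$X
  X0[!design$mask] <- 0
  miss_cols <- which(colSums(!design$mask) > 0L)
  if (length(miss_cols)) {
    ind <- 1 - design$mask[, miss_cols, drop = FALSE]
    colnames(ind) <- paste0("missing_", colnames(design$X)[miss_cols])
    X0 <- cbind(X0, ind)
  }
  X0
}

#' Fit the Bayesian neural network classifier
#'
#' Posterior over the weights of a `p -> hidden -> 1` logistic network by
#' mean-field variational inference; the predictive probability of steady
#' work is the posterior average of the network's sigmoid output.
#'
#' @param design An `sw_design`.
#' @param arch A [bnn_architecture()].
#' @param draws,iters,mc_samples,lr,seed As in [fit_sparse_logistic()].
#' @return An `sw_fit` (family `"bnn"`); `coef_draws` is `NULL` (the
#'   network does not expose per-predictor odds ratios), the pointwise
#'   `log_lik` matrix follows the shared evaluation contract.
#' @export
fit_bnn <- function(design, arch = bnn_architecture(), draws = 1000L,
                    iters = 3000L, mc_samples = 2L, lr = 0.02, seed = 1L) {
  stopifnot(inherits(arch, "sw_bnn_arch"))
  if (draws < 100L) stop("draws must be at least 100", call. = FALSE)
  if (!all(design$y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  X <- .bnn_inputs(design)
  y <- design$y
  n <- nrow(X); p <- ncol(X); H <- arch$hidden
  ps2 <- arch$weight_prior_sd^2
  d <- p * H + H + H + 1L
  i_W1 <- seq_len(p * H)
  i_b1 <- p * H + seq_len(H)
  i_w2 <- p * H + H + seq_len(H)
  i_b2 <- d
  t0 <- Sys.time()

  lpg <- function(theta) {
    S <- ncol(theta)
    logp <- numeric(S)
    gr <- matrix(0, d, S)
    for (s in seq_len(S)) {
      th <- theta[, s]
      W1 <- matrix(th[i_W1], p, H)
      b1 <- th[i_b1]; w2 <- th[i_w2]; b2 <- th[i_b2]
      A <- sweep(X %*% W1, 2, b1, `+`)
      Hh <- tanh(A)
      eta <- drop(Hh %*% w2) + b2
      if (!all(is.finite(eta))) stop("non-finite network output during optimization",
                                     call. = FALSE)
      logp[s] <- sum(y * .log_sigmoid(eta) + (1 - y) * .log_sigmoid(-eta)) -
        sum(th^2) / (2 * ps2)
      r <- y - stats::plogis(eta)
      gw2 <- drop(crossprod(Hh, r))
      gA <- (r %o% w2) * (1 - Hh^2)
      gr[i_W1, s] <- as.vector(crossprod(X, gA))
      gr[i_b1, s] <- colSums(gA)
      gr[i_w2, s] <- gw2
      gr[i_b2, s] <- sum(r)
      gr[, s] <- gr[, s] - th / ps2
    }
    list(logp = logp, grad = gr)
  }

  # Random (seeded) initialization of the variational means breaks the
  # hidden-unit permutation symmetry; a zero start stalls in its saddle.
  init_mu <- withr_seed(seed + 2L, stats::rnorm(d, 0, 0.5))
  vi <- advi(lpg, d, iters = iters, mc_samples = mc_samples, lr = lr,
             seed = seed, init_mu = init_mu, init_log_sigma = -2.3)
  if (isFALSE(vi$converged)) {
    warning("variational fit did not meet the ELBO convergence criterion",
            call. = FALSE)
  }
  theta <- .advi_draws(vi, draws, seed = seed + 1L)

  log_lik <- matrix(NA_real_, draws, n)
  for (s in seq_len(draws)) {
    th <- theta[, s]
    W1 <- matrix(th[i_W1], p, H)
    A <- sweep(X %*% W1, 2, th[i_b1], `+`)
    eta <- drop(tanh(A) %*% th[i_w2]) + th[i_b2]
    log_lik[s, ] <- y * .log_sigmoid(eta) + (1 - y) * .log_sigmoid(-eta)
  }

  structure(list(
    family = "bnn",
    parameters = list(theta = t(theta), arch = arch,
                      input_columns = colnames(X)),
    coef_draws = NULL,
    log_lik = log_lik, y = y, participant = design$participant,
    wave = design$wave, predictor_set = design$predictor_set,
    diagnostics = list(method = "vi", converged = vi$converged,
                       elbo_trace = vi$elbo_trace, seed = seed, draws = draws,
                       runtime_s = as.numeric(Sys.time() - t0, units = "secs"))
  ), class = "sw_fit")
}
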