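# Shared fixtures: all built in code, deterministically.

# A bare design object around a given matrix, bypassing build_design, for
# unit tests of the likelihood and fitting layers.
make_design <- function(X, y, participant = seq_len(nrow(X)),
                        wave = rep(1L, nrow(X)),
                        kinds = rep("baseline", ncol(X))) {
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (ncol(X) == 0) colnames(X) <- character(0)
  structure(list(
    X = X, mask = !is.na(X), y = as.integer(y),
    participant = participant, wave = wave,
    column_kind = stats::setNames(kinds, colnames(X)),
    scaling = NULL, predictor_set = "full", m_max = 14, n_dropped = 0
  ), class = "sw_design")
}

# A small cohort config (fast to generate) with the default calibration
# targets but fewer participants; calibration optional.
small_config <- function(n = 300, seed = 1L, calibrate = FALSE) {
  default_generator_config(n_participants = n, seed = seed,
                           calibrate = calibrate)
}

# Posterior-mean fitted probability of the positive class per observation,
# recovered from the pointwise log-likelihood matrix.
fitted_prob <- function(fit) {
  pl <- exp(fit$log_lik)
  p1 <- sweep(pl, 2, fit$y, function(p, y) ifelse(y == 1, p, 1 - p))
  colMeans(p1)
}

# A generator config whose outcome depends only on the named coefficients.
config_with_coefficients <- function(co, n = 400, seed = 1L,
                                     random_intercept_sd = 0.5) {
  base <- c(intercept_wave1 = -1.6, intercept_wave2 = -1.6,
            intercept_wave3 = -1.6)
  generator_config(
    n_participants = n,
    scales = steadywork:::default_scale_specs(),
    medical = steadywork:::default_medical_specs(),
    true_coefficients = c(base, co),
    random_intercept_sd = random_intercept_sd,
    seed = seed
  )
}
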