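sim_design <- function(n, beta, intercept = -1, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("x%02d", seq_len(p))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  make_design(X, y)
}

test_that("an intercept-only fit recovers the logit of the prevalence", {
  set.seed(5)
  y <- rbinom(4000, 1, 0.173)
  d <- make_design(matrix(numeric(0), 4000, 0), y)
  f <- fit_sparse_logistic(d, hierarchical = FALSE, iters = 800, seed = 2)
  expect_lt(abs(mean(f$parameters$alpha) - qlogis(mean(y))), 0.1)
})

test_that("variational fits are deterministic under a fixed seed", {
  d <- sim_design(300, c(0.8, 0, -0.5), seed = 3)
  f1 <- fit_sparse_logistic(d, hierarchical = FALSE, iters = 500, seed = 11)
  f2 <- fit_sparse_logistic(d, hierarchical = FALSE, iters = 500, seed = 11)
  expect_identical(f1$coef_draws, f2$coef_draws)
  expect_identical(summarize_odds_ratios(f1), summarize_odds_ratios(f2))
  f3 <- fit_sparse_logistic(d, hierarchical = FALSE, iters = 500, seed = 12)
  expect_false(identical(f1$coef_draws, f3$coef_draws))
})

test_that("sparse slopes are recovered on a moderate simulated design", {
  beta <- c(1.0, 0, 0, -0.8, 0, 0, 0.5, 0)
  d <- sim_design(1200, beta, seed = 7)
  f <- fit_sparse_logistic(d, hierarchical = FALSE, iters = 1500, seed = 4)
  est <- colMeans(f$coef_draws)
  expect_lt(median(abs(est[c(1, 4, 7)] - beta[c(1, 4, 7)])), 0.15)
  expect_lt(max(abs(est[beta == 0])), 0.25)
})

test_that("shrinking the global scale drives all slopes toward zero", {
  # weak effects: the evidence for nonzero slopes is a few nats, so a tiny
  # global scale can overcome it and collapse the model
  d <- sim_design(250, c(0.4, -0.3, 0.2, 0, 0), seed = 9)
  maxb <- vapply(c(1, 0.05, 0.001), function(gs) {
    f <- fit_sparse_logistic(
      d, prior = prior_config(global_scale = gs),
      hierarchical = FALSE, iters = 3000, seed = 5
    )
    max(abs(colMeans(f$coef_draws)))
  }, 0)
  expect_true(all(diff(maxb) < 0))
  expect_lt(maxb[3], 0.1)
})

test_that("the missing-value model marginalizes over latent covariates", {
  # independent predictors, one partially missing; the per-column Gaussian
  # missing-value model is then correctly specified, so the latent scheme
  # should keep the slope estimates close to the complete-data fit
  set.seed(21)
  n <- 900
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.9 * X[, 1] - 0.7 * X[, 2]))
  d_full <- make_design(X, y)
  Xm <- X
  Xm[sample(n, 250), "x2"] <- NA
  d_miss <- make_design(Xm, y)
  f_full <- fit_sparse_logistic(d_full, hierarchical = FALSE, iters = 1200, seed = 6)
  f_miss <- fit_sparse_logistic(d_miss, hierarchical = FALSE, iters = 1200, seed = 6)
  expect_lt(max(abs(colMeans(f_full$coef_draws) - colMeans(f_miss$coef_draws))),
            0.15)
  # latent draws exist for every missing cell
  expect_equal(ncol(f_miss$parameters$x_mis), 250)
  # pointwise log-likelihood covers all observations with finite values
  expect_true(all(is.finite(f_miss$log_lik)))
})

test_that("a participant random intercept absorbs within-person persistence", {
  set.seed(31)
  n_subj <- 250
  u <- rnorm(n_subj, 0, 1.2)
  subj <- rep(seq_len(n_subj), each = 3)
  X <- matrix(rnorm(length(subj)), ncol = 1, dimnames = list(NULL, "x1"))
  y <- rbinom(length(subj), 1, plogis(-1 + 0.6 * X[, 1] + u[subj]))
  d <- make_design(X, y, participant = subj, wave = rep(1:3, n_subj))
  f <- fit_sparse_logistic(d, hierarchical = TRUE, iters = 1500, seed = 8)
  expect_gt(mean(f$parameters$sigma_u), 0.5)
  expect_equal(ncol(f$parameters$u), n_subj)
})

test_that("odds-ratio summaries follow the lognormal identities and ranking", {
  fake <- structure(list(coef_draws = cbind(
    zero = rep(0, 4000),
    up = rnorm(4000, 0.7, 0.1),
    down = rnorm(4000, -0.5, 0.05),
    small = rnorm(4000, 0.2, 0.05)
  )), class = "sw_fit")
  s <- summarize_odds_ratios(fake)
  z <- s[s$predictor == "zero", ]
  expect_equal(z$or_mean, 1)
  expect_equal(c(z$or_low, z$or_high), c(1, 1))
  expect_equal(s$or_mean[s$predictor == "up"], exp(0.7 + 0.1^2 / 2),
               tolerance = 0.02)
  # |log OR| ranking regardless of sign, ties broken alphabetically
  expect_equal(s$predictor, c("up", "down", "small", "zero"))
  expect_error(summarize_odds_ratios(structure(list(coef_draws = NULL),
                                               class = "sw_fit")),
               "does not expose")
})

test_that("the mcmc validation path agrees with glm on simple data", {
  d <- sim_design(200, c(0.8, -0.4), intercept = 0.2, seed = 13)
  f <- fit_sparse_logistic(d, prior = prior_config("normal", slope_scale = 10),
                           method = "mcmc", hierarchical = FALSE,
                           draws = 1500, seed = 3)
  ml <- glm(d$y ~ d$X, family = binomial)
  expect_lt(max(abs(c(mean(f$parameters$alpha), colMeans(f$coef_draws)) -
                      coef(ml))), 0.15)
  expect_true(f$diagnostics$accept_rate > 0.1 &&
                f$diagnostics$accept_rate < 0.6)
})

test_that("invalid fitting inputs fail loudly", {
  d <- sim_design(50, c(0.5))
  expect_error(fit_sparse_logistic(d, draws = 50), "at least 100")
  expect_error(fit_sparse_logistic(d, method = "mcmc"), "normal slope prior")
  d$y[1] <- 2L
  expect_error(fit_sparse_logistic(d), "binary")
})
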