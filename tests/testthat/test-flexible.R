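test_that("partitions cover observations exactly once and split at quantiles", {
  set.seed(2)
  X <- cbind(a = rnorm(200), b = rnorm(200))
  d <- make_design(X, rbinom(200, 1, 0.4))
  p1 <- define_partition(d, "a", n_bins = 1)
  expect_equal(p1$n_regions, 1)
  expect_true(all(p1$region == 1))
  p2 <- define_partition(d, "a", n_bins = 2)
  expect_equal(p2$n_regions, 2)
  expect_equal(p2$cuts$a, median(X[, "a"]))
  expect_equal(unname(p2$region), ifelse(X[, "a"] <= median(X[, "a"]), 1L, 2L))
  p4 <- define_partition(d, c("a", "b"), n_bins = 2)
  expect_lte(p4$n_regions, 4)
  expect_equal(sum(table(p4$region)), 200)
  # deterministic region ids
  expect_identical(p4$region, define_partition(d, c("a", "b"), 2)$region)
  expect_error(define_partition(d, "zz"), "not in design")
})

test_that("undersized regions are merged with a neighbor", {
  set.seed(6)
  # near-duplicate variables leave the off-diagonal tensor cells nearly
  # empty, forcing the merge rule to fire
  a <- rnorm(100)
  X <- cbind(a = a, b = a + 0.15 * rnorm(100))
  d <- make_design(X, rbinom(100, 1, 0.5))
  expect_message(p <- define_partition(d, c("a", "b"), n_bins = 2),
                 "merging region")
  expect_true(all(table(p$region) >= 10))
  expect_equal(sum(table(p$region)), 100)
})

test_that("a single-region piecewise fit reduces to the global GLM", {
  set.seed(4)
  n <- 1000
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("a", "b", "c")
  y <- rbinom(n, 1, plogis(-0.5 + X %*% c(0.9, -0.6, 0)))
  d <- make_design(X, y)
  part1 <- define_partition(d, "a", n_bins = 1)
  fp <- fit_piecewise(d, part1, hierarchical = FALSE, iters = 1500, seed = 3)
  fg <- fit_sparse_logistic(d, prior = prior_config("normal", slope_scale = 1),
                            hierarchical = FALSE, iters = 1500, seed = 3)
  expect_lt(max(abs(fitted_prob(fp) - fitted_prob(fg))), 0.02)
})

test_that("region-specific slopes recover opposite signs across regions", {
  set.seed(8)
  n <- 1200
  pv <- rnorm(n) # partition variable; median ~ 0
  x <- rnorm(n)
  slope <- ifelse(pv > median(pv), 1, -1)
  y <- rbinom(n, 1, plogis(slope * x))
  d <- make_design(cbind(pv = pv, x = x), y)
  part <- define_partition(d, "pv", n_bins = 2)
  f <- fit_piecewise(d, part, offset_scale = 1, hierarchical = FALSE,
                     iters = 2000, seed = 5)
  # region slope = global + offset; region 1 is pv below the median
  off <- matrix(colMeans(f$parameters$offsets), nrow = 2, byrow = TRUE)
  colnames(off) <- colnames(d$X)
  slope_r <- colMeans(f$coef_draws)["x"] + off[, "x"]
  expect_lt(slope_r[1], -0.4)
  expect_gt(slope_r[2], 0.4)
})

test_that("tiny offset scales collapse the piecewise model onto the global one", {
  set.seed(12)
  n <- 600
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(X %*% c(0.7, -0.3)))
  d <- make_design(X, y)
  part <- define_partition(d, "a", n_bins = 2)
  f <- suppressWarnings(fit_piecewise(d, part, offset_scale = 1e-3,
                                      hierarchical = FALSE, iters = 1200,
                                      seed = 7))
  expect_lt(max(abs(colMeans(f$parameters$offsets))), 0.02)
  expect_lt(max(abs(colMeans(f$parameters$region_intercepts))), 0.02)
})

test_that("the network separates linearly separable toy data", {
  set.seed(3)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2)
  colnames(X) <- c("a", "b")
  y <- as.integer(X[, 1] + X[, 2] + 0.1 * rnorm(n) > 0)
  f <- suppressWarnings(fit_bnn(make_design(X, y), iters = 3000, seed = 2))
  expect_gt(roc_curve(psis_loo(f))$auc, 0.95)
})

test_that("the network beats the linear model on XOR-patterned data", {
  set.seed(3)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2)
  colnames(X) <- c("a", "b")
  y <- as.integer(X[, 1] * X[, 2] > 0) # no linear decision boundary
  d <- make_design(X, y)
  f_bnn <- fit_bnn(d, iters = 4000, seed = 1)
  f_lin <- fit_sparse_logistic(d, hierarchical = FALSE, iters = 1500, seed = 1)
  auc_bnn <- roc_curve(psis_loo(f_bnn))$auc
  auc_lin <- roc_curve(psis_loo(f_lin))$auc
  expect_gt(auc_bnn - auc_lin, 0.2)
})

test_that("architecture and input validation fail loudly", {
  expect_error(bnn_architecture(hidden = 0), "positive")
  expect_error(bnn_architecture(activation = "relu"), "tanh")
  expect_equal(bnn_architecture()$hidden, 12L)
  d <- make_design(cbind(a = rnorm(30)), rbinom(30, 1, 0.5))
  expect_error(fit_bnn(d, draws = 10), "at least 100")
  # missing cells become zero-fill plus indicator columns
  Xm <- cbind(a = c(NA, rnorm(29)), b = rnorm(30))
  dm <- make_design(Xm, rbinom(30, 1, 0.5))
  expect_equal(colnames(steadywork:::.bnn_inputs(dm)), c("a", "b", "missing_a"))
  expect_equal(steadywork:::.bnn_inputs(dm)[1, "a"], 0, ignore_attr = TRUE)
  expect_equal(steadywork:::.bnn_inputs(dm)[1, "missing_a"], 1, ignore_attr = TRUE)
})
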