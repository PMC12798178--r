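test_that("the Bernoulli-logit log-likelihood matches hand arithmetic", {
  X <- cbind(x1 = c(1, -2, 0.5), x2 = c(0, 1, -1))
  d <- make_design(X, y = c(1L, 0L, 1L))
  par <- list(intercept = 0.3, coefficients = c(x1 = 0.8, x2 = -0.4))
  eta <- 0.3 + X %*% c(0.8, -0.4)
  expect_equal(log_likelihood(d, par),
               as.numeric(ifelse(c(1, 0, 1) == 1, plogis(eta, log.p = TRUE),
                                 plogis(-eta, log.p = TRUE))),
               tolerance = 1e-12)
  # all coefficients zero: every observation contributes log(1/2)
  par0 <- list(intercept = 0, coefficients = c(x1 = 0, x2 = 0))
  expect_equal(log_likelihood(d, par0), rep(log(0.5), 3))
  # saturation: a huge eta with y = 1 contributes about zero
  dsat <- make_design(cbind(x1 = 50), y = 1L)
  expect_gt(log_likelihood(dsat, list(intercept = 0, coefficients = c(x1 = 2))),
            -1e-10)
  expect_error(log_likelihood(make_design(X, c(1L, 2L, 0L)), par), "binary")
})

test_that("discrete marginalization equals exact mixture enumeration", {
  # binary surrogate covariate: log of the exact two-term mixture
  X <- cbind(x1 = c(NA, 1), x2 = c(0.5, -0.5))
  d <- make_design(X, y = c(1L, 0L))
  par <- list(intercept = -0.2, coefficients = c(x1 = 0.9, x2 = 0.4))
  mm <- list(x1 = list(type = "discrete", values = c(0, 1), probs = c(0.3, 0.7)))
  got <- marginalized_log_likelihood(d, par, mm)
  eta0 <- -0.2 + 0 * 0.9 + 0.5 * 0.4
  eta1 <- -0.2 + 1 * 0.9 + 0.5 * 0.4
  expect_equal(got[1], log(0.3 * plogis(eta0) + 0.7 * plogis(eta1)),
               tolerance = 1e-12)
  # fully observed row reduces to the plain likelihood
  expect_equal(got[2], log_likelihood(make_design(X[2, , drop = FALSE], 0L), par),
               tolerance = 1e-12)
})

test_that("marginalization matches brute-force enumeration on many rows", {
  set.seed(42)
  n <- 50; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", 1:p)
  # up to 3 missing cells per row
  for (i in seq_len(n)) {
    k <- sample(0:3, 1)
    if (k) X[i, sample(p, k)] <- NA
  }
  y <- rbinom(n, 1, 0.4)
  d <- make_design(X, y)
  par <- list(intercept = 0.1,
              coefficients = setNames(c(1.2, -0.7, 0.3, 0.5), colnames(X)))
  vals <- list(values = c(-2, -1, 0, 1, 2), probs = c(0.1, 0.2, 0.4, 0.2, 0.1))
  mm <- setNames(replicate(p, c(list(type = "discrete"), vals),
                           simplify = FALSE), colnames(X))
  got <- marginalized_log_likelihood(d, par, mm)
  # independent oracle: expand.grid over every missing cell of each row
  oracle <- vapply(seq_len(n), function(i) {
    mis <- which(is.na(X[i, ]))
    if (!length(mis)) {
      eta <- 0.1 + sum(X[i, ] * par$coefficients)
      return(ifelse(y[i] == 1, plogis(eta, log.p = TRUE), plogis(-eta, log.p = TRUE)))
    }
    grid <- do.call(expand.grid, replicate(length(mis), vals$values,
                                           simplify = FALSE))
    wgrid <- do.call(expand.grid, replicate(length(mis), vals$probs,
                                            simplify = FALSE))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      xi <- X[i, ]
      xi[mis] <- as.numeric(grid[g, ])
      eta <- 0.1 + sum(xi * par$coefficients)
      tot <- tot + prod(as.numeric(wgrid[g, ])) * (if (y[i] == 1) plogis(eta) else plogis(-eta))
    }
    log(tot)
  }, 0)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("point masses and irrelevant Gaussian cells reduce cleanly", {
  X <- cbind(x1 = c(NA, NA), x2 = c(1, -1))
  y <- c(1L, 0L)
  d <- make_design(X, y)
  par <- list(intercept = 0, coefficients = c(x1 = 0.6, x2 = -0.3))
  # point mass: equals the plain likelihood at that value
  mm_pt <- list(x1 = list(type = "point", value = 0.25))
  Xf <- X; Xf[, "x1"] <- 0.25
  expect_equal(marginalized_log_likelihood(d, par, mm_pt),
               log_likelihood(make_design(Xf, y), par), tolerance = 1e-12)
  # Gaussian cell with zero coefficient: marginalizing an unused variable
  par0 <- list(intercept = 0, coefficients = c(x1 = 0, x2 = -0.3))
  mm_g <- list(x1 = list(type = "gaussian", mean = 0, sd = 1.5))
  Xz <- X; Xz[, "x1"] <- 0
  expect_equal(marginalized_log_likelihood(d, par0, mm_g),
               log_likelihood(make_design(Xz, y), par0), tolerance = 1e-10)
  # an undeclared missing cell is an error
  expect_error(marginalized_log_likelihood(d, par, list()), "no declared")
})

test_that("with an all-true mask the marginalized and plain likelihood agree", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  colnames(X) <- c("a", "b", "c")
  d <- make_design(X, rbinom(20, 1, 0.5))
  par <- list(intercept = -0.5,
              coefficients = c(a = 0.4, b = -1.1, c = 0.2))
  mm <- list(a = list(type = "gaussian", mean = 0, sd = 1))
  expect_identical(marginalized_log_likelihood(d, par, mm),
                   log_likelihood(d, par))
})

test_that("Gauss-Hermite marginalization matches dense Riemann integration", {
  X <- cbind(x1 = NA_real_, x2 = 0.8)
  d <- make_design(X, 1L)
  par <- list(intercept = -1, coefficients = c(x1 = 0.7, x2 = 0.5))
  mm <- list(x1 = list(type = "gaussian", mean = 0.3, sd = 1.2, nodes = 31))
  got <- marginalized_log_likelihood(d, par, mm)
  z <- seq(-8, 8, length.out = 20001)
  fx <- dnorm(z, 0.3, 1.2) * plogis(-1 + 0.7 * z + 0.5 * 0.8)
  expect_equal(got, log(sum(fx) * diff(z)[1]), tolerance = 1e-7)
})
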