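# Sparse hierarchical Bayesian logistic regression for annual steady-work
# odds: regularized-horseshoe slopes, participant random intercepts, and
# latent missing-covariate values sampled jointly with the coefficients
# ("averaging over estimates of the missing values"). Inference is
# mean-field variational by default, with an MCMC path for validation-scale
# problems.

#' Prior configuration for the Bayesian logistic models
#'
#' @param slope_prior `"horseshoe"` (regularized horseshoe: sparsity-inducing
#'   continuous shrinkage with a finite slab) or `"normal"`.
#' @param global_scale Scale of the half-Cauchy prior on the horseshoe's
#'   global shrinkage parameter tau.
#' @param slab_scale Slab width c of the regularized horseshoe: even fully
#'   unshrunk coefficients are effectively bounded by a Normal(0, c) slab.
#' @param slope_scale SD of the Normal slope prior when
#'   `slope_prior = "normal"`.
#' @param intercept_scale SD of the Normal prior on the intercept and on
#'   unpenalized (wave) coefficients.
#' @param random_intercept_scale Scale of the half-Normal hyperprior on the
#'   participant random-intercept SD.
#' @param missing_location_scale SD of the Normal hyperprior on each
#'   missing-value model's column location (columns are standardized, so a
#'   weakly-informative sub-unit scale is appropriate).
#' @param missing_log_scale_sd SD of the Normal prior on each column's log
#'   missing-value scale.
#' @return An object of class `sw_prior`.
#' @export
prior_config <- function(slope_prior = c("horseshoe", "normal"),
                         global_scale = 1, slab_scale = 2, slope_scale = 2,
                         intercept_scale = 2, random_intercept_scale = 1,
                         missing_location_scale = 0.5,
                         missing_log_scale_sd = 0.5) {
  slope_prior <- match.arg(slope_prior)
  vals <- c(global_scale, slab_scale, slope_scale, intercept_scale,
            random_intercept_scale, missing_location_scale, missing_log_scale_sd)
  if (any(vals <= 0)) stop("all prior scales must be positive", call. = FALSE)
  structure(list(
    slope_prior = slope_prior, global_scale = global_scale,
    slab_scale = slab_scale, slope_scale = slope_scale,
    intercept_scale = intercept_scale,
    random_intercept_scale = random_intercept_scale,
    missing_location_scale = missing_location_scale,
    missing_log_scale_sd = missing_log_scale_sd
  ), class = "sw_prior")
}

# Assemble the data pieces the gradient callbacks need.
.model_data <- function(design) {
  X <- design$X
  mask <- design$mask
  X0 <- X
  X0[!mask] <- 0
  mis <- which(!mask, arr.ind = TRUE)
  subj <- match(design$participant, unique(design$participant))
  pen <- which(!design$column_kind %in% "wave")
  unp <- which(design$column_kind %in% "wave")
  mis_col_levels <- sort(unique(mis[, 2L]))
  list(
    X0 = X0, y = design$y, n = nrow(X), p = ncol(X),
    subj = subj, n_subj = max(subj),
    pen = pen, unp = unp,
    mr = mis[, 1L], mc = mis[, 2L], M = nrow(mis),
    mis_cols = mis_col_levels,
    mis_colgrp = match(mis[, 2L], mis_col_levels),
    C = length(mis_col_levels)
  )
}

# Parameter layout over the unconstrained vector; returns index accessors.
.param_layout <- function(md, prior, hierarchical) {
  idx <- list(); pos <- 0L
  take <- function(nm, k) {
    idx[[nm]] <<- if (k > 0L) pos + seq_len(k) else integer()
    pos <<- pos + k
  }
  take("alpha", 1L)
  take("b_unp", length(md$unp))
  pp <- length(md$pen)
  if (prior$slope_prior == "horseshoe") {
    take("z", pp); take("loglam", pp); take("logtau", 1L)
  } else {
    take("b_pen", pp)
  }
  if (hierarchical) { take("uraw", md$n_subj); take("logsigu", 1L) }
  if (md$M > 0L) { take("xm", md$M); take("muc", md$C); take("logsc", md$C) }
  idx$d <- pos
  idx
}

# Joint log density and gradient, vectorized over the columns of `theta`
# (d x S matrix). Returns list(logp = S-vector, grad = d x S).
.logistic_logp_grad <- function(theta, md, prior, idx, hierarchical) {
  S <- ncol(theta)
  gr <- matrix(0, nrow(theta), S)
  A <- theta[idx$alpha, , drop = FALSE]
  B <- matrix(0, md$p, S)
  logp <- numeric(S)

  if (length(md$unp)) {
    Bu <- theta[idx$b_unp, , drop = FALSE]
    B[md$unp, ] <- Bu
  }
  if (prior$slope_prior == "horseshoe") {
    Z <- theta[idx$z, , drop = FALSE]
    L <- theta[idx$loglam, , drop = FALSE]
    Tt <- theta[idx$logtau, , drop = FALSE]
    cc <- prior$slab_scale
    tmat <- exp(sweep(L, 2, Tt[1, ], `+`))
    denom <- cc^2 + tmat^2
    m <- cc * tmat / sqrt(denom)
    Bp <- m * Z
  } else {
    Bp <- theta[idx$b_pen, , drop = FALSE]
  }
  B[md$pen, ] <- Bp

  eta <- md$X0 %*% B
  eta <- sweep(eta, 2, A[1, ], `+`)
  if (md$M > 0L) {
    xm <- theta[idx$xm, , drop = FALSE]
    contrib <- xm * B[md$mc, , drop = FALSE]
    rs <- rowsum(contrib, md$mr)
    rows <- as.integer(rownames(rs))
    eta[rows, ] <- eta[rows, ] + rs
  }
  if (hierarchical) {
    Uraw <- theta[idx$uraw, , drop = FALSE]
    lsu <- theta[idx$logsigu, , drop = TRUE]
    sigu <- exp(lsu)
    U <- sweep(Uraw, 2, sigu, `*`)
    eta <- eta + U[md$subj, , drop = FALSE]
  }

  ll <- md$y * .log_sigmoid(eta) + (1 - md$y) * .log_sigmoid(-eta)
  logp <- colSums(ll)
  r <- md$y - stats::plogis(eta)

  gB <- crossprod(md$X0, r) # p x S
  if (md$M > 0L) {
    gBm <- rowsum(xm * r[md$mr, , drop = FALSE], md$mc)
    colsb <- as.integer(rownames(gBm))
    gB[colsb, ] <- gB[colsb, ] + gBm
  }

  gr[idx$alpha, ] <- colSums(r) - A / prior$intercept_scale^2
  logp <- logp - colSums(A^2) / (2 * prior$intercept_scale^2)
  if (length(md$unp)) {
    gr[idx$b_unp, ] <- gB[md$unp, , drop = FALSE] - Bu / prior$intercept_scale^2
    logp <- logp - colSums(Bu^2) / (2 * prior$intercept_scale^2)
  }

  gBpen <- gB[md$pen, , drop = FALSE]
  if (prior$slope_prior == "horseshoe") {
    dm_dl <- (cc^3 / denom^1.5) * tmat # d m / d log(lambda) (= d/d log tau per j)
    lam2 <- exp(2 * L)
    tau <- exp(Tt[1, ])
    tr2 <- (tau / prior$global_scale)^2
    gr[idx$z, ] <- gBpen * m - Z
    gr[idx$loglam, ] <- gBpen * Z * dm_dl + 1 - 2 * lam2 / (1 + lam2)
    gr[idx$logtau, ] <- colSums(gBpen * Z * dm_dl) + 1 - 2 * tr2 / (1 + tr2)
    logp <- logp - colSums(Z^2) / 2 +
      colSums(L - log1p(lam2)) + (Tt[1, ] - log1p(tr2))
  } else {
    gr[idx$b_pen, ] <- gBpen - Bp / prior$slope_scale^2
    logp <- logp - colSums(Bp^2) / (2 * prior$slope_scale^2)
  }

  if (hierarchical) {
    gu <- rowsum(r, md$subj) # n_subj x S
    rs2 <- prior$random_intercept_scale^2
    gr[idx$uraw, ] <- sweep(gu, 2, sigu, `*`) - Uraw
    gr[idx$logsigu, ] <- colSums(gu * Uraw) * sigu - sigu^2 / rs2 + 1
    logp <- logp - colSums(Uraw^2) / 2 - sigu^2 / (2 * rs2) + lsu
  }

  if (md$M > 0L) {
    muc <- theta[idx$muc, , drop = FALSE]
    logsc <- theta[idx$logsc, , drop = FALSE]
    sc <- exp(logsc)
    mu_cell <- muc[md$mis_colgrp, , drop = FALSE]
    s_cell <- sc[md$mis_colgrp, , drop = FALSE]
    dev <- (xm - mu_cell) / s_cell^2
    gr[idx$xm, ] <- r[md$mr, , drop = FALSE] * B[md$mc, , drop = FALSE] - dev
    gdev <- rowsum(dev, md$mis_colgrp)
    gr[idx$muc, ] <- gdev - muc / prior$missing_location_scale^2
    sq <- rowsum((xm - mu_cell)^2 / s_cell^2, md$mis_colgrp)
    ncell <- tabulate(md$mis_colgrp, md$C)
    gr[idx$logsc, ] <- sq - ncell - logsc / prior$missing_log_scale_sd^2
    logp <- logp - colSums((xm - mu_cell)^2 / (2 * s_cell^2)) -
      colSums(logsc[md$mis_colgrp, , drop = FALSE]) -
      colSums(muc^2) / (2 * prior$missing_location_scale^2) -
      colSums(logsc^2) / (2 * prior$missing_log_scale_sd^2)
  }

  list(logp = logp, grad = gr)
}

# Transform unconstrained draws (d x S) into interpretable parameter draws.
.extract_draws <- function(theta, md, prior, idx, hierarchical, colnames_X) {
  S <- ncol(theta)
  B <- matrix(0, md$p, S)
  if (length(md$unp)) B[md$unp, ] <- theta[idx$b_unp, , drop = FALSE]
  if (prior$slope_prior == "horseshoe") {
    cc <- prior$slab_scale
    tmat <- exp(sweep(theta[idx$loglam, , drop = FALSE], 2,
                      theta[idx$logtau, , drop = TRUE], `+`))
    B[md$pen, ] <- (cc * tmat / sqrt(cc^2 + tmat^2)) *
      theta[idx$z, , drop = FALSE]
  } else {
    B[md$pen, ] <- theta[idx$b_pen, , drop = FALSE]
  }
  rownames(B) <- colnames_X
  out <- list(alpha = theta[idx$alpha, , drop = TRUE], beta = t(B))
  if (hierarchical) {
    sigu <- exp(theta[idx$logsigu, , drop = TRUE])
    out$u <- t(sweep(theta[idx$uraw, , drop = FALSE], 2, sigu, `*`))
    out$sigma_u <- sigu
  }
  if (md$M > 0L) out$x_mis <- t(theta[idx$xm, , drop = FALSE])
  out
}

# Per-draw linear predictor (S x n) from extracted parameter draws.
.linear_predictor_draws <- function(par, md) {
  eta <- par$beta %*% t(md$X0) # S x n
  eta <- eta + par$alpha
  if (!is.null(par$x_mis) && md$M > 0L) {
    contrib <- t(par$x_mis) * t(par$beta)[md$mc, , drop = FALSE] # M x S
    rs <- rowsum(contrib, md$mr)
    rows <- as.integer(rownames(rs))
    eta[, rows] <- eta[, rows] + t(rs)
  }
  if (!is.null(par$u)) eta <- eta + par$u[, md$subj, drop = FALSE]
  eta
}

#' Fit the sparse hierarchical Bayesian logistic regression
#'
#' The paper-facing model: Bernoulli-logit likelihood for steady work per
#' participant-year, regularized-horseshoe priors on the standardized
#' slopes (so impactful predictors can be read off by coefficient
#' magnitude), Normal priors on the intercept and wave terms, an optional
#' participant-level random intercept for the repeated annual outcomes, and
#' a per-column Gaussian missing-value model whose latent missing cells are
#' sampled jointly with the coefficients.
#'
#' @param design An `sw_design` from [build_design()].
#' @param prior An [prior_config()].
#' @param method `"vi"` (mean-field variational, the default) or `"mcmc"`
#'   (adaptive random-walk Metropolis; validation-scale only -- requires a
#'   normal slope prior, no hierarchy, and no missing cells).
#' @param draws Posterior draws to retain (>= 100).
#' @param iters Optimization steps (VI) or retained iterations (MCMC).
#' @param mc_samples Monte Carlo samples per VI step.
#' @param lr Base learning rate for VI.
#' @param hierarchical Include the participant random intercept.
#' @param seed Integer seed; VI fits are deterministic given the seed.
#' @return An object of class `sw_fit`: posterior parameter draws
#'   (`parameters$beta` is draws x columns on the standardized log-odds
#'   scale), the pointwise log-likelihood matrix `log_lik` (draws x
#'   observations, with latent missing values integrated per draw), and
#'   inference metadata (`diagnostics$converged` flags non-convergence
#'   rather than failing silently).
#' @export
fit_sparse_logistic <- function(design, prior = prior_config(),
                                method = c("vi", "mcmc"), draws = 1000L,
                                iters = 2000L, mc_samples = 2L, lr = 0.02,
                                hierarchical = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (draws < 100L) stop("draws must be at least 100", call. = FALSE)
  if (!all(design$y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  md <- .model_data(design)
  t0 <- Sys.time()

  if (method == "mcmc") {
    if (prior$slope_prior != "normal" || md$M > 0L) {
      stop("method = 'mcmc' supports the normal slope prior without missing cells",
           call. = FALSE)
    }
    if (hierarchical) {
      stop("method = 'mcmc' does not support the participant random intercept",
           call. = FALSE)
    }
    d <- 1L + md$p
    logp <- function(th) {
      eta <- th[1L] + drop(md$X0 %*% th[-1L])
      sum(md$y * .log_sigmoid(eta) + (1 - md$y) * .log_sigmoid(-eta)) -
        th[1L]^2 / (2 * prior$intercept_scale^2) -
        sum(th[-1L]^2) / (2 * prior$slope_scale^2)
    }
    mc <- rw_metropolis(logp, init = rep(0, d), draws = draws,
                        warmup = max(1000L, iters), thin = 3L, seed = seed)
    theta <- t(mc$draws)
    idx <- list(alpha = 1L)
    par <- list(alpha = theta[1L, ], beta = t(theta[-1L, , drop = FALSE]))
    colnames(par$beta) <- colnames(design$X)
    diagnostics <- list(method = "mcmc", accept_rate = mc$accept_rate,
                        converged = mc$accept_rate > 0.05)
  } else {
    idx <- .param_layout(md, prior, hierarchical)
    lpg <- function(theta) .logistic_logp_grad(theta, md, prior, idx, hierarchical)
    vi <- advi(lpg, idx$d, iters = iters, mc_samples = mc_samples, lr = lr,
               seed = seed)
    theta <- .advi_draws(vi, draws, seed = seed + 1L)
    par <- .extract_draws(theta, md, prior, idx, hierarchical, colnames(design$X))
    diagnostics <- list(method = "vi", converged = vi$converged,
                        elbo_trace = vi$elbo_trace, iters = iters)
    if (isFALSE(vi$converged)) {
      warning("variational fit did not meet the ELBO convergence criterion",
              call. = FALSE)
    }
  }

  eta <- .linear_predictor_draws(par, md) # draws x n
  log_lik <- sweep(.log_sigmoid(eta), 2, md$y, `*`) +
    sweep(.log_sigmoid(-eta), 2, 1 - md$y, `*`)

  structure(list(
    family = "logistic",
    parameters = par,
    coef_draws = par$beta,
    log_lik = log_lik,
    y = design$y, participant = design$participant, wave = design$wave,
    predictor_set = design$predictor_set,
    prior = prior, hierarchical = hierarchical,
    diagnostics = c(diagnostics,
                    list(seed = seed, draws = draws,
                         runtime_s = as.numeric(Sys.time() - t0, units = "secs")))
  ), class = "sw_fit")
}

#' @export
print.sw_fit <- function(x, ...) {
  cat("<sw_fit> family:", x$family,
      " method:", x$diagnostics$method,
      " predictor set:", x$predictor_set, "\n")
  cat("  draws:", nrow(x$log_lik), " observations:", ncol(x$log_lik),
      " converged:", x$diagnostics$converged, "\n")
  if (!is.null(x$coef_draws)) {
    top <- utils::head(summarize_odds_ratios(x), 5L)
    cat("  top predictors by |log OR|:",
        paste(top$predictor, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior odds-ratio summary and effect ranking
#'
#' Because every continuous predictor is standardized, coefficient
#' magnitudes -- and hence odds ratios per SD of predictor -- are directly
#' comparable, and predictors are ranked by the magnitude of their
#' posterior mean log odds ratio (ties broken alphabetically).
#'
#' @param fit An `sw_fit` with coefficient draws (linear or piecewise
#'   global coefficients).
#' @return A data frame with one row per predictor: posterior mean odds
#'   ratio `or_mean`, equal-tailed 95% credible interval `or_low`/`or_high`,
#'   `log_or_mean`, and `rank` (1 = largest magnitude), sorted by rank.
#' @export
summarize_odds_ratios <- function(fit) {
  if (is.null(fit$coef_draws)) {
    stop("this model family does not expose coefficient draws", call. = FALSE)
  }
  B <- fit$coef_draws
  if (!nrow(B)) stop("empty draws", call. = FALSE)
  orr <- exp(B)
  out <- data.frame(
    predictor = colnames(B),
    or_mean = colMeans(orr),
    or_low = apply(orr, 2, stats::quantile, 0.025),
    or_high = apply(orr, 2, stats::quantile, 0.975),
    log_or_mean = colMeans(B),
    row.names = NULL
  )
  ord <- order(-abs(out$log_or_mean), out$predictor)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
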