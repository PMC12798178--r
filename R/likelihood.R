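# Bernoulli-logit likelihood, with exact marginalization over declared
# missing-covariate distributions (enumeration / Gauss-Hermite quadrature)
# used to validate the latent-variable scheme inside the samplers.

# Numerically stable log(sigma(eta)) and log(1 - sigma(eta)).
.log_sigmoid <- function(eta) ifelse(eta > 0, -log1p(exp(-eta)), eta - log1p(exp(eta)))

# Per-observation Bernoulli-logit log-likelihood at a linear predictor.
.bernoulli_loglik <- function(y, eta) {
  y * .log_sigmoid(eta) + (1 - y) * .log_sigmoid(-eta)
}

# Gauss-Hermite nodes/weights (probabilists' form, integrates against the
# standard normal density) via the Golub-Welsch eigendecomposition.
.gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L))
  J[cbind(1:(n - 1L), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

.resolve_params <- function(design, params) {
  co <- params$coefficients
  if (is.null(names(co))) stop("coefficients must be named", call. = FALSE)
  bad <- setdiff(names(co), colnames(design$X))
  if (length(bad)) {
    stop("coefficient(s) not in design: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  u <- rep(0, nrow(design$X))
  if (!is.null(params$random_intercepts)) {
    u <- params$random_intercepts[as.character(design$participant)]
    if (anyNA(u)) stop("random_intercepts must cover every participant", call. = FALSE)
  }
  list(alpha = if (is.null(params$intercept)) 0 else params$intercept,
       co = co, u = u)
}

#' Per-observation log-likelihood under a coefficient assignment
#'
#' Computes the Bernoulli-logit log-likelihood
#' `log p(y_i) = y_i log sigma(eta_i) + (1 - y_i) log(1 - sigma(eta_i))`
#' with `eta = intercept + X beta (+ participant random intercept)`. All
#' used columns must be observed; use [marginalized_log_likelihood()] when
#' they are not.
#'
#' @param design An `sw_design`.
#' @param params List with `intercept` (scalar), `coefficients` (named
#'   vector over design columns), and optionally `random_intercepts`
#'   (named by participant id).
#' @return Numeric vector, one log-likelihood per design row.
#' @export
log_likelihood <- function(design, params) {
  y <- design$y
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  p <- .resolve_params(design, params)
  Xu <- design$X[, names(p$co), drop = FALSE]
  if (anyNA(Xu)) {
    stop("missing values among used columns; use marginalized_log_likelihood",
         call. = FALSE)
  }
  eta <- p$alpha + drop(Xu %*% p$co) + p$u
  .bernoulli_loglik(y, eta)
}

#' Log-likelihood marginalized over missing covariates
#'
#' Returns `log integral p(y | x_obs, x_mis, theta) p(x_mis) dx_mis` per
#' observation, where each missing cell among the used columns carries a
#' declared distribution: a point mass, a discrete distribution (exact
#' mixture), or a Gaussian (Gauss-Hermite quadrature). Cells are treated as
#' independent; the grid is the tensor product over an observation's
#' missing cells.
#'
#' @param design An `sw_design`.
#' @param params As in [log_likelihood()].
#' @param missing_model Named list, one entry per column that may be
#'   missing: `list(type = "point", value =)`, `list(type = "discrete",
#'   values =, probs =)`, or `list(type = "gaussian", mean =, sd =,
#'   nodes = 21)`.
#' @param max_cells Maximum missing cells per observation before erroring
#'   (the tensor grid grows exponentially); default 6.
#' @return Numeric vector of per-observation marginal log-likelihoods.
#' @export
marginalized_log_likelihood <- function(design, params, missing_model,
                                        max_cells = 6L) {
  y <- design$y
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  p <- .resolve_params(design, params)
  used <- names(p$co)
  Xu <- design$X[, used, drop = FALSE]
  if (!anyNA(Xu)) {
    # bitwise-identical to the plain likelihood when nothing is missing
    return(log_likelihood(design, params))
  }
  out <- numeric(nrow(Xu))
  cell_dist <- function(col) {
    d <- missing_model[[col]]
    if (is.null(d)) {
      stop("missing cell in column ", col, " has no declared distribution",
           call. = FALSE)
    }
    switch(d$type,
      point = list(values = d$value, logw = 0),
      discrete = {
        if (abs(sum(d$probs) - 1) > 1e-8) stop("discrete probs must sum to 1", call. = FALSE)
        list(values = d$values, logw = log(d$probs))
      },
      gaussian = {
        gh <- .gauss_hermite(if (is.null(d$nodes)) 21L else d$nodes)
        list(values = d$mean + d$sd * gh$nodes, logw = log(gh$weights))
      },
      stop("unknown missing-model type: ", d$type, call. = FALSE)
    )
  }
  for (i in seq_len(nrow(Xu))) {
    xi <- Xu[i, ]
    mis <- which(is.na(xi))
    if (!length(mis)) {
      eta <- p$alpha + sum(xi * p$co) + p$u[i]
      out[i] <- .bernoulli_loglik(y[i], eta)
      next
    }
    if (length(mis) > max_cells) {
      stop("observation ", i, " has ", length(mis),
           " missing cells (max_cells = ", max_cells, ")", call. = FALSE)
    }
    dists <- lapply(used[mis], cell_dist)
    # tensor grid: accumulate eta contributions and log-weights
    eta_base <- p$alpha + sum(xi[-mis] * p$co[-mis]) + p$u[i]
    grid_eta <- 0; grid_logw <- 0
    for (k in seq_along(mis)) {
      d <- dists[[k]]
      contrib <- d$values * p$co[[mis[k]]]
      grid_eta <- outer(grid_eta, contrib, `+`)
      grid_logw <- outer(grid_logw, d$logw, `+`)
    }
    ll <- .bernoulli_loglik(y[i], eta_base + as.vector(grid_eta)) +
      as.vector(grid_logw)
    m <- max(ll)
    out[i] <- m + log(sum(exp(ll - m)))
  }
  out
}
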