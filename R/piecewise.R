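# Piecewise (local-region) Bayesian GLM: a quantile tensor-product partition
# of chosen design columns, with per-region coefficient offsets shrunk
# toward global coefficients. Relaxes the single-linear-predictor assumption
# while staying piecewise linear.

#' Define a quantile tensor-product partition of a design
#'
#' Each partition variable is cut at empirical quantiles into `n_bins`
#' intervals; regions are the tensor product of the per-variable bins.
#' Regions with fewer than 10 observations are merged into the previous
#' nonempty region (logged via `message()`). Region ids are deterministic
#' functions of the design and arguments.
#'
#' @param design An `sw_design`.
#' @param variables Columns to partition on. The special name
#'   `"mental_baseline_composite"` uses the mean of the standardized mental
#'   scale baselines (Communication & Cognition, Resilience, Interpersonal,
#'   Mood), a coarse overall mental-function axis. The default (`NULL`)
#'   partitions on the mental composite and baseline age when the design
#'   carries functional columns, otherwise on baseline age alone.
#' @param n_bins Quantile bins per variable (>= 1).
#' @return An object of class `sw_partition`: `variables`, `cuts` (per
#'   variable), `region` (integer per observation), `n_regions`.
#' @export
define_partition <- function(design, variables = NULL, n_bins = 2L) {
  if (n_bins < 1L) stop("n_bins must be at least 1", call. = FALSE)
  if (is.null(variables)) {
    has_mental <- any(paste0(MENTAL_SCALES, "_baseline") %in% colnames(design$X))
    variables <- if (has_mental) {
      c("mental_baseline_composite", "age_baseline")
    } else "age_baseline"
  }
  vals <- lapply(variables, function(v) {
    if (v == "mental_baseline_composite") {
      cols <- intersect(paste0(MENTAL_SCALES, "_baseline"), colnames(design$X))
      if (!length(cols)) {
        stop("design has no mental baseline columns for the composite", call. = FALSE)
      }
      x <- rowMeans(design$X[, cols, drop = FALSE], na.rm = TRUE)
      x[!is.finite(x)] <- 0
      x
    } else {
      if (!v %in% colnames(design$X)) {
        stop("partition variable not in design: ", v, call. = FALSE)
      }
      x <- design$X[, v]
      if (anyNA(x)) {
        stop("partition variable ", v,
             " has missing values; impute or choose observed variables", call. = FALSE)
      }
      x
    }
  })
  names(vals) <- variables
  cuts <- lapply(vals, function(x) {
    if (n_bins == 1L) return(numeric(0))
    unique(stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                           names = FALSE, type = 7))
  })
  bin <- mapply(function(x, ct) {
    findInterval(x, ct) + 1L
  }, vals, cuts, SIMPLIFY = FALSE)
  region <- Reduce(function(a, b) (a - 1L) * n_bins + b, bin)
  region <- match(region, sort(unique(region)))
  # merge undersized regions into the previous one
  repeat {
    counts <- tabulate(region)
    small <- which(counts > 0L & counts < 10L)
    if (!length(small) || length(unique(region)) == 1L) break
    s <- small[1L]
    target <- if (s > 1L) s - 1L else s + 1L
    message("merging region ", s, " (", counts[s],
            " observations) into region ", target)
    region[region == s] <- target
    region <- match(region, sort(unique(region)))
  }
  structure(list(variables = variables, cuts = cuts, region = region,
                 n_regions = length(unique(region))),
            class = "sw_partition")
}

#' @export
print.sw_partition <- function(x, ...) {
  cat("<sw_partition> ", x$n_regions, " regions over ",
      paste(x$variables, collapse = " x "), "\n", sep = "")
  print(table(region = x$region))
  invisible(x)
}

# Joint log density + gradient for the piecewise model (see fit_piecewise).
.piecewise_logp_grad <- function(theta, md, prior, idx, hierarchical,
                                 region, offset_scale) {
  S <- ncol(theta)
  gr <- matrix(0, nrow(theta), S)
  R <- max(region)
  use_offsets <- !is.null(idx$aoff) # single-region fits carry no offsets
  A <- theta[idx$alpha, , drop = FALSE]
  Bg <- theta[idx$bglob, , drop = FALSE] # p x S global slopes

  rows_by_region <- split(seq_len(md$n), region)
  eta <- md$X0 %*% Bg
  eta <- sweep(eta, 2, A[1, ], `+`)
  if (use_offsets) {
    Aoff <- theta[idx$aoff, , drop = FALSE] # R x S region intercept offsets
    Doff <- theta[idx$doff, , drop = FALSE] # (R*p) x S region slope offsets
    Dr <- vector("list", R)
    for (r in seq_len(R)) {
      Dr[[r]] <- Doff[(r - 1L) * md$p + seq_len(md$p), , drop = FALSE]
      rows <- rows_by_region[[as.character(r)]]
      eta[rows, ] <- eta[rows, ] + md$X0[rows, , drop = FALSE] %*% Dr[[r]]
      eta[rows, ] <- sweep(eta[rows, , drop = FALSE], 2, Aoff[r, ], `+`)
    }
  }
  if (md$M > 0L) {
    xm <- theta[idx$xm, , drop = FALSE]
    reg_m <- region[md$mr]
    coef_cell <- Bg[md$mc, , drop = FALSE]
    if (use_offsets) {
      coef_cell <- coef_cell + Doff[(reg_m - 1L) * md$p + md$mc, , drop = FALSE]
    }
    rs <- rowsum(xm * coef_cell, md$mr)
    rws <- as.integer(rownames(rs))
    eta[rws, ] <- eta[rws, ] + rs
  }
  if (hierarchical) {
    Uraw <- theta[idx$uraw, , drop = FALSE]
    lsu <- theta[idx$logsigu, , drop = TRUE]
    sigu <- exp(lsu)
    eta <- eta + sweep(Uraw, 2, sigu, `*`)[md$subj, , drop = FALSE]
  }

  ll <- md$y * .log_sigmoid(eta) + (1 - md$y) * .log_sigmoid(-eta)
  logp <- colSums(ll)
  rr <- md$y - stats::plogis(eta)

  gBg <- crossprod(md$X0, rr)
  if (use_offsets) {
    for (r in seq_len(R)) {
      rows <- rows_by_region[[as.character(r)]]
      gD <- crossprod(md$X0[rows, , drop = FALSE], rr[rows, , drop = FALSE])
      gr[idx$doff[(r - 1L) * md$p + seq_len(md$p)], ] <-
        gD - Dr[[r]] / offset_scale^2
      gr[idx$aoff[r], ] <- colSums(rr[rows, , drop = FALSE]) -
        Aoff[r, ] / offset_scale^2
    }
    logp <- logp - colSums(Aoff^2) / (2 * offset_scale^2) -
      colSums(Doff^2) / (2 * offset_scale^2)
  }
  if (md$M > 0L) {
    gxm_lik <- rr[md$mr, , drop = FALSE] * coef_cell
    gm <- rowsum(xm * rr[md$mr, , drop = FALSE], md$mc)
    colsb <- as.integer(rownames(gm))
    gBg[colsb, ] <- gBg[colsb, ] + gm
    if (use_offsets) {
      # region-offset gradient from latent cells
      grp <- (reg_m - 1L) * md$p + md$mc
      gmo <- rowsum(xm * rr[md$mr, , drop = FALSE], grp)
      gidx <- as.integer(rownames(gmo))
      gr[idx$doff[gidx], ] <- gr[idx$doff[gidx], ] + gmo
    }
  }
  gr[idx$alpha, ] <- colSums(rr) - A / prior$intercept_scale^2
  gr[idx$bglob, ] <- gBg - Bg / prior$slope_scale^2
  logp <- logp - colSums(A^2) / (2 * prior$intercept_scale^2) -
    colSums(Bg^2) / (2 * prior$slope_scale^2)

  if (hierarchical) {
    gu <- rowsum(rr, md$subj)
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
    gr[idx$xm, ] <- gxm_lik - dev
    gr[idx$muc, ] <- rowsum(dev, md$mis_colgrp) -
      muc / prior$missing_location_scale^2
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

#' Fit the piecewise Bayesian logistic regression
#'
#' Fits, in effect, a separate logistic regression to each local region of
#' the data: the linear predictor for an observation in region r is
#' `alpha + a_r + x (beta + delta_r)`, with Normal priors on the global
#' coefficients and Normal(0, `offset_scale`) shrinkage pulling each
#' region's offsets toward the global model. As `offset_scale` approaches 0
#' the model collapses to a single global GLM. Missing covariate cells are
#' handled by the same latent Gaussian scheme as the linear model.
#'
#' @param design An `sw_design`.
#' @param partition An [define_partition()] result on this design.
#' @param prior An [prior_config()] (the `slope_scale` applies to global
#'   slopes; default 1 via `prior_config(slope_prior = "normal",
#'   slope_scale = 1)` is used when `prior` is `NULL`).
#' @param offset_scale Prior SD of the region offsets (default 0.5).
#' @param draws,iters,mc_samples,lr,hierarchical,seed As in
#'   [fit_sparse_logistic()].
#' @return An `sw_fit` (family `"piecewise"`). `coef_draws` holds the
#'   *global* coefficient draws; `parameters$offsets` is a draws x (regions
#'   x columns) matrix and `parameters$region_intercepts` the per-region
#'   intercept offsets.
#' @export
fit_piecewise <- function(design, partition, prior = NULL, offset_scale = 0.5,
                          draws = 1000L, iters = 2000L, mc_samples = 2L,
                          lr = 0.02, hierarchical = TRUE, seed = 1L) {
  stopifnot(inherits(partition, "sw_partition"))
  if (length(partition$region) != nrow(design$X)) {
    stop("partition was not defined on this design", call. = FALSE)
  }
  if (is.null(prior)) prior <- prior_config("normal", slope_scale = 1)
  if (draws < 100L) stop("draws must be at least 100", call. = FALSE)
  md <- .model_data(design)
  region <- partition$region
  R <- max(region)
  t0 <- Sys.time()

  idx <- list(); pos <- 0L
  take <- function(nm, k) { idx[[nm]] <<- pos + seq_len(k); pos <<- pos + k }
  take("alpha", 1L); take("bglob", md$p)
  if (R > 1L) { take("aoff", R); take("doff", R * md$p) }
  if (hierarchical) { take("uraw", md$n_subj); take("logsigu", 1L) }
  if (md$M > 0L) { take("xm", md$M); take("muc", md$C); take("logsc", md$C) }

  lpg <- function(theta) {
    .piecewise_logp_grad(theta, md, prior, idx, hierarchical, region, offset_scale)
  }
  vi <- advi(lpg, pos, iters = iters, mc_samples = mc_samples, lr = lr, seed = seed)
  if (isFALSE(vi$converged)) {
    warning("variational fit did not meet the ELBO convergence criterion",
            call. = FALSE)
  }
  theta <- .advi_draws(vi, draws, seed = seed + 1L)

  Bg <- t(theta[idx$bglob, , drop = FALSE])
  colnames(Bg) <- colnames(design$X)
  par <- list(
    alpha = theta[idx$alpha, ], beta = Bg,
    region_intercepts = if (R > 1L) t(theta[idx$aoff, , drop = FALSE]) else
      matrix(0, draws, 1L),
    offsets = if (R > 1L) t(theta[idx$doff, , drop = FALSE]) else
      matrix(0, draws, md$p)
  )
  if (hierarchical) {
    sigu <- exp(theta[idx$logsigu, ])
    par$u <- t(sweep(theta[idx$uraw, , drop = FALSE], 2, sigu, `*`))
    par$sigma_u <- sigu
  }
  if (md$M > 0L) par$x_mis <- t(theta[idx$xm, , drop = FALSE])

  # per-draw linear predictor including region terms
  eta <- .linear_predictor_draws(par[c("alpha", "beta", "u", "x_mis")], md)
  if (R > 1L) {
    for (r in seq_len(R)) {
      rows <- which(region == r)
      Dr <- t(theta[idx$doff[(r - 1L) * md$p + seq_len(md$p)], , drop = FALSE])
      eta[, rows] <- eta[, rows] + Dr %*% t(md$X0[rows, , drop = FALSE]) +
        par$region_intercepts[, r]
      if (md$M > 0L) {
        cells <- which(region[md$mr] == r)
        for (k in cells) {
          eta[, md$mr[k]] <- eta[, md$mr[k]] + par$x_mis[, k] * Dr[, md$mc[k]]
        }
      }
    }
  }
  log_lik <- sweep(.log_sigmoid(eta), 2, md$y, `*`) +
    sweep(.log_sigmoid(-eta), 2, 1 - md$y, `*`)

  structure(list(
    family = "piecewise", parameters = par, coef_draws = Bg,
    log_lik = log_lik, y = design$y, participant = design$participant,
    wave = design$wave, predictor_set = design$predictor_set,
    prior = prior, hierarchical = hierarchical, partition = partition,
    diagnostics = list(method = "vi", converged = vi$converged,
                       elbo_trace = vi$elbo_trace, seed = seed,
                       draws = draws, offset_scale = offset_scale,
                       runtime_s = as.numeric(Sys.time() - t0, units = "secs"))
  ), class = "sw_fit")
}
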