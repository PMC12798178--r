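# Synthetic cohort generation: seeded longitudinal participant-wave tables
# with the moment structure, cross-scale correlation, informative
# missingness, and logistic outcome model the downstream analysis assumes.

# ---- truncated / censored normal helpers -----------------------------------

# Mean of a standard normal truncated below at a: lambda(a) = phi(a)/(1-Phi(a))
.tnorm_lambda <- function(a) stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)

# Location mu such that a N(mu, sd) truncated below at `floor` has the target
# mean.
.match_truncated_mean <- function(target, sd, floor) {
  f <- function(mu) {
    a <- (floor - mu) / sd
    mu + sd * .tnorm_lambda(a) - target
  }
  stats::uniroot(f, c(target - 6 * sd, target + 2 * sd), tol = 1e-10)$root
}

# Location mu such that max(floor, N(mu, sd)) has the target mean (censoring).
.match_censored_mean <- function(target, sd, floor) {
  f <- function(mu) {
    a <- (floor - mu) / sd
    floor * stats::pnorm(a) + mu * stats::pnorm(a, lower.tail = FALSE) +
      sd * stats::dnorm(a) - target
  }
  stats::uniroot(f, c(target - 6 * sd, target + 2 * sd), tol = 1e-10)$root
}

# Draw n values from N(mu, sd) truncated below at `floor`, along with the
# exactly standardized latent residual (used to correlate follow-up waves
# with baseline).
.rtruncnorm_std <- function(n, mu, sd, floor) {
  a <- (floor - mu) / sd
  u <- stats::runif(n, stats::pnorm(a), 1)
  z <- stats::qnorm(u)
  lam <- .tnorm_lambda(a)
  s_t <- sqrt(1 - lam * (lam - a))
  list(x = mu + sd * z, z_std = (z - lam) / s_t)
}

# Negative-binomial (or Poisson fallback when not overdispersed) quantile
# transform of a standard-normal latent.
.count_from_latent <- function(z, mean, sd) {
  u <- stats::pnorm(z)
  v <- sd^2
  if (v > mean * 1.0001) {
    size <- mean^2 / (v - mean)
    stats::qnbinom(u, size = size, mu = mean)
  } else {
    stats::qpois(u, lambda = mean)
  }
}

# ---- covariate generation ---------------------------------------------------

# Draw everything except the outcome: demographics, complete scale scores,
# medical variables, and Community Mobility presence flags. Returns a list of
# per-component matrices/data frames; RNG state is the caller's.
generate_covariates <- function(config) {
  n <- config$n_participants
  dem <- config$demographics

  # demographics ---------------------------------------------------------
  demo <- data.frame(participant_id = seq_len(n))
  for (f in c("work_history", "education", "housing", "vehicle_access",
              "race", "arm")) {
    p <- dem[[f]]
    demo[[f]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  ar <- (dem$age_range - dem$age_mean) / dem$age_sd
  u <- stats::runif(n, stats::pnorm(ar[1]), stats::pnorm(ar[2]))
  demo$age <- dem$age_mean + dem$age_sd * stats::qnorm(u)

  # function scales -------------------------------------------------------
  R <- scale_correlation_matrix(config)
  L <- chol(R)
  k <- length(FUNCTION_SCALES)
  zb <- matrix(stats::rnorm(n * k), n, k) %*% L
  colnames(zb) <- FUNCTION_SCALES
  bm <- vapply(config$scales, `[[`, 0, "baseline_mean")
  bs <- vapply(config$scales, `[[`, 0, "baseline_sd")
  baseline <- sweep(sweep(zb, 2, bs, `*`), 2, bm, `+`)

  a <- vapply(config$scales, `[[`, 0, "baseline_change_cor")
  changes <- vector("list", 3L)
  for (w in 1:3) {
    eps <- matrix(stats::rnorm(n * k), n, k) %*% L
    zd <- sweep(zb, 2, a, `*`) + sweep(eps, 2, sqrt(1 - a^2), `*`)
    cm <- vapply(config$scales, function(s) s$change_mean_by_wave[w], 0)
    cs <- vapply(config$scales, function(s) s$change_sd_by_wave[w], 0)
    changes[[w]] <- sweep(sweep(zd, 2, cs, `*`), 2, cm, `+`)
  }

  # medical ---------------------------------------------------------------
  med_vals <- list() # each: n x 4 matrix (baseline, years 1-3)
  for (m in config$medical) {
    out <- matrix(NA_real_, n, 4L)
    if (m$family == "truncnorm") {
      mu0 <- .match_truncated_mean(m$wave_means[1], m$wave_sds[1], m$floor)
      b <- .rtruncnorm_std(n, mu0, m$wave_sds[1], m$floor)
      out[, 1L] <- b$x
      for (w in 1:3) {
        loc <- .match_censored_mean(m$wave_means[w + 1], m$wave_sds[w + 1], m$floor)
        e <- stats::rnorm(n)
        y <- loc + m$wave_sds[w + 1] *
          (m$wave_cor * b$z_std + sqrt(1 - m$wave_cor^2) * e)
        out[, w + 1L] <- pmax(m$floor, y)
      }
    } else {
      z0 <- stats::rnorm(n)
      out[, 1L] <- .count_from_latent(z0, m$wave_means[1], m$wave_sds[1])
      for (w in 1:3) {
        zw <- m$wave_cor * z0 + sqrt(1 - m$wave_cor^2) * stats::rnorm(n)
        out[, w + 1L] <- .count_from_latent(zw, m$wave_means[w + 1], m$wave_sds[w + 1])
      }
    }
    med_vals[[m$name]] <- out
  }

  # Community Mobility presence flags -------------------------------------
  mis <- config$missingness
  presence <- list()
  for (nm in c("drive", "ride", "wheelchair")) {
    p <- mis[[paste0(nm, "_presence_by_wave")]]
    presence[[nm]] <- vapply(1:4, function(w) {
      stats::rbinom(n, 1L, p[w])
    }, integer(n))
  }

  list(demo = demo, baseline = baseline, changes = changes,
       medical = med_vals, presence = presence)
}

# Analytic mean/sd of the truncated age distribution (used to standardize
# age on the generator's "true" scale).
.age_moments <- function(dem) {
  a <- (dem$age_range - dem$age_mean) / dem$age_sd
  za <- stats::dnorm(a[1]); zb <- stats::dnorm(a[2])
  pa <- stats::pnorm(a[1]); pb <- stats::pnorm(a[2])
  Z <- pb - pa
  m <- (za - zb) / Z
  v <- 1 + (a[1] * za - a[2] * zb) / Z - m^2
  list(mean = dem$age_mean + dem$age_sd * m, sd = dem$age_sd * sqrt(v))
}

# Implied SD of (x_w - x_0) for a medical spec.
.medical_change_sd <- function(m, w) {
  s0 <- m$wave_sds[1]; sw <- m$wave_sds[w + 1]
  sqrt(max(s0^2 + sw^2 - 2 * m$wave_cor * s0 * sw, 1e-12))
}

# The true-model linear predictor (no intercept, no random intercept) for
# each participant at each follow-up wave, built by standardizing the
# generated covariates with the *configured* moments.
generator_linear_predictor <- function(cov, config) {
  n <- nrow(cov$demo)
  co <- config$true_coefficients
  co <- co[!grepl("^intercept_wave", names(co))]
  eta <- matrix(0, n, 3L)
  if (!length(co)) return(eta)
  am <- .age_moments(config$demographics)
  for (w in 1:3) {
    for (nm in names(co)) {
      b <- co[[nm]]
      if (b == 0) next
      val <-
        if (nm == "age_baseline") {
          (cov$demo$age - am$mean) / am$sd
        } else if (grepl(":", nm, fixed = TRUE)) {
          parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
          as.numeric(cov$demo[[parts[1]]] == parts[2])
        } else if (nm %in% c("wave2", "wave3")) {
          as.numeric(paste0("wave", w + 1) == nm) # wave w is year w
        } else if (nm %in% paste0(FUNCTION_SCALES, "_baseline")) {
          sc <- config$scales[[sub("_baseline$", "", nm)]]
          (cov$baseline[, sc$name] - sc$baseline_mean) / sc$baseline_sd
        } else if (nm %in% paste0(FUNCTION_SCALES, "_change")) {
          sc <- config$scales[[sub("_change$", "", nm)]]
          # a zero change SD makes the change a constant; it contributes 0
          (cov$changes[[w]][, sc$name] - sc$change_mean_by_wave[w]) /
            max(sc$change_sd_by_wave[w], 1e-12)
        } else if (nm %in% c("has_drive", "has_ride", "has_wheelchair")) {
          cov$presence[[sub("^has_", "", nm)]][, w + 1L]
        } else if (nm %in% paste0(names(config$medical), "_baseline")) {
          m <- config$medical[[sub("_baseline$", "", nm)]]
          (cov$medical[[m$name]][, 1L] - m$wave_means[1]) / m$wave_sds[1]
        } else if (nm %in% paste0(names(config$medical), "_change")) {
          m <- config$medical[[sub("_change$", "", nm)]]
          d <- cov$medical[[m$name]][, w + 1L] - cov$medical[[m$name]][, 1L]
          (d - (m$wave_means[w + 1] - m$wave_means[1])) / .medical_change_sd(m, w)
        } else {
          stop("unbuildable coefficient name: ", nm, call. = FALSE)
        }
      eta[, w] <- eta[, w] + b * val
    }
  }
  eta
}

# ---- public generator -------------------------------------------------------

#' Generate a synthetic SED-like longitudinal cohort
#'
#' Draws a complete cohort (4 annual waves per participant: baseline plus 3
#' follow-up years) from the configured moment structure, generates the
#' binary steady-work outcome for each follow-up year from the configured
#' logistic model (with a participant-level random intercept), and then --
#' unless `missingness = FALSE` -- applies the block missingness pattern to
#' the functional scale scores. Community Mobility presence flags are drawn
#' before the outcome, since score presence is itself a covariate of the
#' outcome model.
#'
#' @param config An [generator_config()] object.
#' @param missingness Apply the config's block missingness pattern to the
#'   functional scores (default `TRUE`). Presence flags are drawn either way.
#' @return A `sw_cohort` data frame with `4 * n_participants` rows, columns:
#'   `participant_id`, `wave` (0 = baseline), one column per functional
#'   scale, `has_drive`/`has_ride`/`has_wheelchair`, one column per medical
#'   variable, demographic columns (wave-invariant), and `steady_work`
#'   (`NA` at baseline).
#' @export
generate_cohort <- function(config, missingness = TRUE) {
  stopifnot(inherits(config, "sw_generator_config"))
  set.seed(config$seed)
  cov <- generate_covariates(config)
  n <- config$n_participants

  eta0 <- generator_linear_predictor(cov, config)
  u <- stats::rnorm(n, 0, config$random_intercept_sd)
  yw <- matrix(NA_integer_, n, 3L)
  for (w in 1:3) {
    a <- config$true_coefficients[[paste0("intercept_wave", w)]]
    yw[, w] <- stats::rbinom(n, 1L, stats::plogis(a + eta0[, w] + u))
  }

  rows <- vector("list", 4L)
  for (w in 0:3) {
    d <- data.frame(participant_id = seq_len(n), wave = w)
    for (s in FUNCTION_SCALES) {
      d[[s]] <- if (w == 0) cov$baseline[, s] else
        cov$baseline[, s] + cov$changes[[w]][, s]
    }
    d$has_drive <- cov$presence$drive[, w + 1L]
    d$has_ride <- cov$presence$ride[, w + 1L]
    d$has_wheelchair <- cov$presence$wheelchair[, w + 1L]
    for (m in names(cov$medical)) d[[m]] <- cov$medical[[m]][, w + 1L]
    d$age <- cov$demo$age
    for (f in c("work_history", "education", "housing", "vehicle_access",
                "race", "arm")) {
      d[[f]] <- cov$demo[[f]]
    }
    d$steady_work <- if (w == 0) NA_integer_ else yw[, w]
    rows[[w + 1L]] <- d
  }
  cohort <- do.call(rbind, rows)
  cohort <- cohort[order(cohort$participant_id, cohort$wave), ]
  rownames(cohort) <- NULL
  class(cohort) <- c("sw_cohort", "data.frame")

  if (missingness) {
    cohort <- apply_missingness(cohort, config$missingness,
                                seed = config$seed + 1L,
                                redraw_presence = FALSE)
  }
  cohort
}

#' Apply the block missingness pattern to a complete cohort
#'
#' Per participant, draws one of the observed block patterns -- missing 0,
#' 7, 14, or 21 functional measurements, i.e. whole follow-up waves of the
#' seven modelled scales at a time -- and blanks the corresponding waves'
#' scale scores. Optionally (re)draws the Community Mobility presence flags
#' per wave from their presence probabilities.
#'
#' @param cohort A `sw_cohort` with complete functional scores.
#' @param spec A [missingness_spec()].
#' @param seed Integer seed; the operation is deterministic given the seed.
#' @param redraw_presence Redraw `has_drive`/`has_ride`/`has_wheelchair` from
#'   the spec's presence probabilities (default `TRUE`). [generate_cohort()]
#'   draws the flags before the outcome and therefore keeps them.
#' @return The cohort with `NA` in blanked scale cells.
#' @export
apply_missingness <- function(cohort, spec, seed = 1L, redraw_presence = TRUE) {
  stopifnot(inherits(spec, "sw_missingness_spec"))
  if (anyNA(cohort[cohort$wave > 0, FUNCTION_SCALES])) {
    stop("apply_missingness expects a cohort with complete functional scores",
         call. = FALSE)
  }
  ids <- unique(cohort$participant_id)
  n <- length(ids)
  blanked <- withr_seed(seed, {
    patt <- sample(names(spec$block_pattern_probs), n, replace = TRUE,
                   prob = spec$block_pattern_probs)
    nblank <- as.integer(patt) %/% 7L
    blank_waves <- lapply(nblank, function(k) {
      if (k == 0L) integer() else sort(sample(1:3, k))
    })
    if (redraw_presence) {
      for (nm in c("drive", "ride", "wheelchair")) {
        p <- spec[[paste0(nm, "_presence_by_wave")]]
        for (w in 0:3) {
          idx <- cohort$wave == w
          cohort[[paste0("has_", nm)]][idx] <-
            stats::rbinom(sum(idx), 1L, p[w + 1L])
        }
      }
    }
    blank_waves
  })
  blank <- do.call(rbind, lapply(seq_along(ids), function(i) {
    if (!length(blanked[[i]])) return(NULL)
    data.frame(participant_id = ids[i], wave = blanked[[i]])
  }))
  if (!is.null(blank)) {
    key <- paste(cohort$participant_id, cohort$wave)
    hit <- key %in% paste(blank$participant_id, blank$wave)
    cohort[hit, FUNCTION_SCALES] <- NA_real_
  }
  cohort
}

#' Observed-value moments of a cohort, by variable and wave
#'
#' Computes wave-level means/SDs (ignoring missing values) for every
#' functional scale and medical variable, change-from-baseline moments
#' (change = follow-up minus the same participant's baseline; missing if
#' either is), presence rates of the Community Mobility flags, and
#' steady-work rates per follow-up year plus pooled.
#'
#' @param cohort A `sw_cohort`.
#' @return A data frame with columns `variable`, `wave` (`NA` = pooled),
#'   `stat` (`value_mean`, `value_sd`, `change_mean`, `change_sd`, `rate`),
#'   `value`, `n`. A statistic with no observed values is `NA`, never zero.
#' @export
empirical_moments <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  med_vars <- setdiff(
    names(cohort),
    c("participant_id", "wave", FUNCTION_SCALES,
      "has_drive", "has_ride", "has_wheelchair", "age", "work_history",
      "education", "housing", "vehicle_access", "race", "arm", "steady_work")
  )
  vars <- c(FUNCTION_SCALES, med_vars)
  base <- cohort[cohort$wave == 0, c("participant_id", vars)]
  out <- list()
  add <- function(variable, wave, stat, x) {
    x <- x[!is.na(x)]
    out[[length(out) + 1L]] <<- data.frame(
      variable = variable, wave = wave, stat = stat,
      value = if (length(x) >= ifelse(grepl("sd$", stat), 2L, 1L)) {
        if (grepl("sd$", stat)) stats::sd(x) else mean(x)
      } else NA_real_,
      n = length(x)
    )
  }
  for (v in vars) {
    for (w in 0:3) {
      x <- cohort[[v]][cohort$wave == w]
      add(v, w, "value_mean", x)
      add(v, w, "value_sd", x)
    }
    for (w in 1:3) {
      sub <- cohort[cohort$wave == w, c("participant_id", v)]
      d <- sub[[v]] - base[[v]][match(sub$participant_id, base$participant_id)]
      add(v, w, "change_mean", d)
      add(v, w, "change_sd", d)
    }
  }
  for (flag in c("has_drive", "has_ride", "has_wheelchair")) {
    for (w in 0:3) add(flag, w, "rate", cohort[[flag]][cohort$wave == w])
    add(flag, NA_integer_, "rate", cohort[[flag]])
  }
  for (w in 1:3) add("steady_work", w, "rate", cohort$steady_work[cohort$wave == w])
  add("steady_work", NA_integer_, "rate", cohort$steady_work[cohort$wave > 0])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a cohort as tidy CSV
#'
#' One row per participant-wave; an empty cell encodes a missing value
#' (never a sentinel number).
#'
#' @param cohort A `sw_cohort`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   `sw_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  class(cohort) <- c("sw_cohort", "data.frame")
  cohort
}

#' @export
print.sw_cohort <- function(x, ...) {
  np <- length(unique(x$participant_id))
  cat("<sw_cohort> ", np, " participants x ", nrow(x) / np, " waves\n", sep = "")
  cat("  steady-work rate (years 1-3): ",
      round(mean(x$steady_work[x$wave > 0], na.rm = TRUE), 3), "\n", sep = "")
  miss <- mean(is.na(as.matrix(x[x$wave > 0, FUNCTION_SCALES])))
  cat("  missing follow-up function cells: ", round(100 * miss, 1), "%\n", sep = "")
  invisible(x)
}
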