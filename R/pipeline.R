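# End-to-end orchestration: cohort -> designs -> fits (predictor sets x
# model families) -> LOO evaluation -> comparison/report files.

MODEL_FAMILIES <- c("logistic", "piecewise", "bnn")

# Small polynomial rolling hash of a serialized R object, for output
# provenance (not cryptographic).
.config_hash <- function(obj) {
  b <- as.integer(serialize(obj, NULL, version = 2L))
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline run configuration
#'
#' @param generator An `sw_generator_config`, a path to a generator YAML, or
#'   a path to a cohort CSV (real-data mode: any table matching the cohort
#'   column dictionary).
#' @param m_max Missing-functioning tolerance for the analysis (default 14,
#'   the most inclusive setting short of accepting fully unobserved
#'   follow-up function).
#' @param sets Predictor sets to run (subset of
#'   `demographic`, `demographic+function`, `demographic+medical`, `full`).
#' @param families Model families to run (subset of `logistic`,
#'   `piecewise`, `bnn`).
#' @param inference Inference settings: `draws`, `iters`, `bnn_iters`,
#'   `mc_samples`, `lr`, `hierarchical`.
#' @param seed Global seed (stage seeds are derived from it).
#' @return A list of class `sw_run_config`.
#' @export
run_config <- function(generator = default_generator_config(),
                       m_max = 14,
                       sets = PREDICTOR_SETS,
                       families = MODEL_FAMILIES,
                       inference = list(),
                       seed = 1L) {
  if (!length(sets) || !length(families)) {
    stop("at least one predictor set and one model family are required",
         call. = FALSE)
  }
  sets <- match.arg(sets, PREDICTOR_SETS, several.ok = TRUE)
  families <- match.arg(families, MODEL_FAMILIES, several.ok = TRUE)
  inf <- utils::modifyList(
    list(draws = 1000L, iters = 2000L, bnn_iters = 3000L, mc_samples = 2L,
         lr = 0.02, hierarchical = TRUE),
    inference
  )
  structure(list(generator = generator, m_max = m_max, sets = sets,
                 families = families, inference = inf, seed = as.integer(seed)),
            class = "sw_run_config")
}

.resolve_cohort <- function(config) {
  gen <- config$generator
  if (inherits(gen, "sw_generator_config")) {
    gen$seed <- config$seed
    return(generate_cohort(gen))
  }
  if (is.character(gen) && length(gen) == 1L) {
    if (!file.exists(gen)) stop("input not readable: ", gen, call. = FALSE)
    if (grepl("\\.ya?ml$", gen)) {
      g <- read_generator_config(gen)
      g$seed <- config$seed
      return(generate_cohort(g))
    }
    return(read_cohort(gen))
  }
  stop("generator must be a generator config or a file path", call. = FALSE)
}

.fit_one <- function(family, design, inf, seed) {
  switch(family,
    logistic = fit_sparse_logistic(
      design, draws = inf$draws, iters = inf$iters,
      mc_samples = inf$mc_samples, lr = inf$lr,
      hierarchical = inf$hierarchical, seed = seed
    ),
    piecewise = fit_piecewise(
      design, define_partition(design), draws = inf$draws, iters = inf$iters,
      mc_samples = inf$mc_samples, lr = inf$lr,
      hierarchical = inf$hierarchical, seed = seed
    ),
    bnn = fit_bnn(
      design, draws = inf$draws, iters = inf$bnn_iters,
      mc_samples = inf$mc_samples, lr = inf$lr, seed = seed
    ),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, builds a standardized design per
#' requested predictor set, fits every requested model family on each,
#' computes PSIS-LOO predictive probabilities and ROC/PR areas, and -- when
#' `out_dir` is given -- writes odds-ratio tables, curve coordinates, the
#' comparison table, and a JSON provenance report. A failing grid cell is
#' recorded and skipped, never fatal to the whole grid.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   file output.
#' @return An `sw_run_report`: list with `comparison` (an
#'   [compare_models()] table), `fits`, `loos`, `odds_ratios` (per linear
#'   fit), `failures`, and `provenance` (config hash, seed, versions).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sw_run_config"))
  t0 <- Sys.time()
  hash <- .config_hash(config[c("generator", "m_max", "sets", "families",
                                "inference", "seed")])
  cohort <- .resolve_cohort(config)
  designs <- lapply(config$sets, function(s) {
    build_design(cohort, s, m_max = config$m_max)
  })
  names(designs) <- config$sets

  fits <- list(); loos <- list(); failures <- list()
  cell_seed <- config$seed
  for (s in config$sets) {
    for (fam in config$families) {
      label <- paste(fam, s, sep = " | ")
      cell_seed <- cell_seed + 1L
      res <- tryCatch(
        {
          f <- .fit_one(fam, designs[[s]], config$inference, cell_seed)
          list(fit = f, loo = psis_loo(f))
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[label]] <- conditionMessage(res)
        message("cell failed: ", label, " (", conditionMessage(res), ")")
      } else {
        fits[[label]] <- res$fit
        loos[[label]] <- res$loo
      }
    }
  }
  if (!length(loos)) stop("every grid cell failed", call. = FALSE)
  comparison <- compare_models(loos)
  odds_ratios <- lapply(fits[vapply(fits, function(f) f$family == "logistic", TRUE)],
                        summarize_odds_ratios)

  report <- structure(list(
    comparison = comparison, fits = fits, loos = loos,
    odds_ratios = odds_ratios, failures = failures,
    provenance = list(
      config_hash = hash, seed = config$seed, m_max = config$m_max,
      n_participants = length(unique(cohort$participant_id)),
      package_version = as.character(utils::packageVersion("steadywork")),
      r_version = R.version.string,
      runtime_s = as.numeric(Sys.time() - t0, units = "secs")
    )
  ), class = "sw_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- function(f) file.path(out_dir, paste0(f, "_", hash, ".csv"))
    utils::write.csv(comparison, tag("model_comparison"), row.names = FALSE)
    for (nm in names(odds_ratios)) {
      safe <- gsub("[^a-z0-9]+", "_", nm)
      utils::write.csv(odds_ratios[[nm]], tag(paste0("odds_ratios_", safe)),
                       row.names = FALSE)
    }
    curves <- do.call(rbind, lapply(names(loos), function(nm) {
      rc <- roc_curve(loos[[nm]])$points
      pc <- pr_curve(loos[[nm]])$points
      rbind(
        data.frame(model = nm, curve = "roc", x = rc$fpr, y = rc$tpr,
                   threshold = rc$threshold),
        data.frame(model = nm, curve = "pr", x = pc$recall, y = pc$precision,
                   threshold = pc$threshold)
      )
    }))
    utils::write.csv(curves, tag("curves"), row.names = FALSE)
    preds <- do.call(rbind, lapply(names(loos), function(nm) {
      lo <- loos[[nm]]
      data.frame(model = nm,
                 participant = fits[[nm]]$participant,
                 wave = fits[[nm]]$wave,
                 steady_work = attr(lo, "y"),
                 loo_prob = lo$prob, pareto_k = lo$pareto_k)
    }))
    utils::write.csv(preds, tag("loo_predictions"), row.names = FALSE)
    jsonlite::write_json(
      c(report$provenance, list(failures = failures)),
      file.path(out_dir, paste0("report_", hash, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' @export
print.sw_run_report <- function(x, ...) {
  cat("<sw_run_report> config", x$provenance$config_hash,
      "seed", x$provenance$seed, "\n")
  print(as.data.frame(x$comparison))
  if (length(x$failures)) {
    cat("  failed cells:", paste(names(x$failures), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Missingness-tolerance sensitivity of the linear model
#'
#' Refits the sparse logistic model on the same cohort while retaining
#' participants with at most 0, 7, and 14 missing functioning measurements,
#' and tabulates the posterior mean log odds ratios side by side. Small
#' differences indicate the in-model marginalization over missing values is
#' benign.
#'
#' @param config An [run_config()]; the linear family must be enabled.
#' @param m_grid Tolerances to compare (default `c(0, 7, 14)`).
#' @param set Predictor set to use (default `"full"`).
#' @return List with `table` (predictor x tolerance matrix of posterior
#'   mean log-ORs), `max_abs_diff` (largest pairwise difference across
#'   tolerances, over predictors), and `skipped` (tolerances whose subset
#'   was empty or failed).
#' @export
sensitivity_missingness <- function(config = run_config(), m_grid = c(0, 7, 14),
                                    set = "full") {
  stopifnot(inherits(config, "sw_run_config"))
  if (!"logistic" %in% config$families) {
    stop("the linear (logistic) family must be enabled", call. = FALSE)
  }
  cohort <- .resolve_cohort(config)
  inf <- config$inference
  cols <- list(); skipped <- character()
  for (m in m_grid) {
    res <- tryCatch({
      d <- build_design(cohort, set, m_max = m)
      f <- fit_sparse_logistic(d, draws = inf$draws, iters = inf$iters,
                               mc_samples = inf$mc_samples, lr = inf$lr,
                               hierarchical = inf$hierarchical,
                               seed = config$seed)
      s <- summarize_odds_ratios(f)
      stats::setNames(s$log_or_mean, s$predictor)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, as.character(m))
      message("m_max = ", m, " skipped: ", conditionMessage(res))
    } else {
      cols[[as.character(m)]] <- res
    }
  }
  if (!length(cols)) stop("all tolerances failed", call. = FALSE)
  preds <- sort(unique(unlist(lapply(cols, names))))
  tab <- vapply(cols, function(v) v[preds], numeric(length(preds)))
  rownames(tab) <- preds
  # wave terms track each subset's per-year prevalence rather than a
  # predictor effect; the headline difference is over shared predictors
  shared <- stats::complete.cases(tab) & !preds %in% c("wave2", "wave3")
  max_abs_diff <- if (ncol(tab) >= 2L && any(shared)) {
    max(apply(tab[shared, , drop = FALSE], 1, function(r) diff(range(r))))
  } else NA_real_
  list(table = tab, max_abs_diff = max_abs_diff, skipped = skipped)
}
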