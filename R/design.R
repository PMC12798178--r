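# Standardized baseline + change-from-baseline design matrices with
# missingness masks, Community Mobility presence indicators, and the four
# nested predictor-set restrictions.

PREDICTOR_SETS <- c("demographic", "demographic+function",
                    "demographic+medical", "full")

#' Change-from-baseline table for a cohort
#'
#' For every continuous variable (functional scales and medical variables),
#' computes `change(w) = value(w) - value(0)` for follow-up waves 1-3.
#' A change is missing whenever either operand is missing.
#'
#' @param cohort A `sw_cohort`.
#' @return A data frame with `participant_id`, `wave` (1-3), and one
#'   `<variable>_change` column per continuous variable.
#' @export
compute_changes <- function(cohort) {
  vars <- intersect(
    c(FUNCTION_SCALES,
      setdiff(names(cohort),
              c("participant_id", "wave", FUNCTION_SCALES, "has_drive",
                "has_ride", "has_wheelchair", "age", "work_history",
                "education", "housing", "vehicle_access", "race", "arm",
                "steady_work"))),
    names(cohort)
  )
  base <- cohort[cohort$wave == 0, c("participant_id", vars)]
  fu <- cohort[cohort$wave %in% 1:3, c("participant_id", "wave", vars)]
  idx <- match(fu$participant_id, base$participant_id)
  if (anyNA(idx)) {
    stop("participant(s) lacking a baseline (wave 0) row: ",
         paste(utils::head(unique(fu$participant_id[is.na(idx)]), 5), collapse = ", "),
         call. = FALSE)
  }
  out <- fu[c("participant_id", "wave")]
  for (v in vars) out[[paste0(v, "_change")]] <- fu[[v]] - base[[v]][idx]
  rownames(out) <- NULL
  out
}

#' Fit standardization parameters for a design's continuous columns
#'
#' Means and sample SDs (n-1 convention) are computed over observed entries
#' only; indicator/dummy columns are marked unscaled and left untouched.
#'
#' @param values Numeric matrix (may contain `NA`).
#' @param kinds Character vector per column: `"baseline"`, `"change"`, or
#'   `"indicator"`. Indicator columns are never rescaled.
#' @return An object of class `sw_scaling`: per-column `center`, `scale`,
#'   `kind`.
#' @export
fit_scaling <- function(values, kinds) {
  stopifnot(is.matrix(values), length(kinds) == ncol(values))
  center <- rep(0, ncol(values))
  scl <- rep(1, ncol(values))
  names(center) <- names(scl) <- colnames(values)
  for (j in seq_len(ncol(values))) {
    if (kinds[j] == "indicator") next
    x <- values[, j]
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      stop("column ", colnames(values)[j],
           " has fewer than 2 observed values; cannot standardize", call. = FALSE)
    }
    s <- stats::sd(x)
    if (s < 1e-12) {
      stop("zero-variance continuous column: ", colnames(values)[j], call. = FALSE)
    }
    center[j] <- mean(x)
    scl[j] <- s
  }
  structure(list(center = center, scale = scl, kind = kinds),
            class = "sw_scaling")
}

#' Apply / invert standardization
#'
#' @param values Numeric matrix with columns matching the scaling object.
#' @param scaling An `sw_scaling` from [fit_scaling()].
#' @return Matrix of the same shape.
#' @export
standardize <- function(values, scaling) {
  sweep(sweep(values, 2, scaling$center, `-`), 2, scaling$scale, `/`)
}

#' @rdname standardize
#' @export
unstandardize <- function(values, scaling) {
  sweep(sweep(values, 2, scaling$scale, `*`), 2, scaling$center, `+`)
}

# Reference-coded dummy expansion for one demographic factor: reference =
# most frequent level in the analysis sample.
.dummy_columns <- function(x, name) {
  tab <- sort(table(x), decreasing = TRUE)
  lev <- names(tab)
  out <- vapply(lev[-1L], function(l) as.numeric(x == l), numeric(length(x)))
  colnames(out) <- paste0(name, ":", lev[-1L])
  out
}

#' Build a standardized design matrix for one predictor set
#'
#' Rows are participant follow-up years with an observed steady-work
#' outcome. Participants missing more than `m_max` functional measurements
#' (over the seven modelled scales, all waves) are dropped. Community
#' Mobility enters only through current-wave presence indicators. Columns
#' are restricted to the requested predictor set (demographics and wave
#' dummies are always included), then standardized per [fit_scaling()]:
#' continuous baselines and changes to mean 0 / SD 1 over observed entries
#' (changes pooled across waves), indicators left as 0/1.
#'
#' @param cohort A `sw_cohort`.
#' @param set Predictor set: `"demographic"`, `"demographic+function"`,
#'   `"demographic+medical"`, or `"full"`.
#' @param m_max Missing-functioning tolerance; one of 0, 7, 14, 21.
#' @param scaling Optional pre-fitted `sw_scaling` (e.g. to score new data
#'   on a fitted model's scale); fitted on the analysis sample when `NULL`.
#' @return An object of class `sw_design`: list with matrix `X` (`NA` where
#'   unobserved), logical `mask` (`TRUE` = observed), outcome `y`,
#'   `participant`, `wave`, `column_kind`, `scaling`, `predictor_set`,
#'   `n_dropped` participants removed by the filter.
#' @export
build_design <- function(cohort, set = "full", m_max = 14, scaling = NULL) {
  if (!set %in% PREDICTOR_SETS) {
    stop("unknown predictor set: ", set, " (expected one of ",
         paste(PREDICTOR_SETS, collapse = ", "), ")", call. = FALSE)
  }
  if (!m_max %in% c(0, 7, 14, 21)) {
    stop("m_max must be one of 0, 7, 14, 21", call. = FALSE)
  }
  med_vars <- setdiff(
    names(cohort),
    c("participant_id", "wave", FUNCTION_SCALES, "has_drive", "has_ride",
      "has_wheelchair", "age", "work_history", "education", "housing",
      "vehicle_access", "race", "arm", "steady_work")
  )

  # missing-functioning filter (count over all waves incl. baseline)
  nmiss <- rowsum(rowSums(is.na(cohort[, FUNCTION_SCALES, drop = FALSE])) + 0,
                  cohort$participant_id)
  keep_ids <- rownames(nmiss)[nmiss[, 1] <= m_max]
  n_dropped <- nrow(nmiss) - length(keep_ids)
  cohort <- cohort[as.character(cohort$participant_id) %in% keep_ids, ]
  if (!nrow(cohort)) stop("no participants remain after the m_max filter", call. = FALSE)

  cohort <- cohort[order(cohort$participant_id, cohort$wave), ]
  changes <- compute_changes(cohort)
  base <- cohort[cohort$wave == 0, ]
  fu <- cohort[cohort$wave %in% 1:3, ]
  stopifnot(identical(changes$participant_id, fu$participant_id),
            identical(as.integer(changes$wave), as.integer(fu$wave)))
  ok <- !is.na(fu$steady_work)
  fu <- fu[ok, ]
  ch <- changes[ok, ]
  bidx <- match(fu$participant_id, base$participant_id)

  cols <- list()
  kinds <- character()
  push <- function(x, name, kind) {
    cols[[name]] <<- x
    kinds[name] <<- kind
  }
  # demographics (always)
  push(base$age[bidx], "age_baseline", "baseline")
  for (f in c("work_history", "education", "housing", "vehicle_access",
              "race", "arm")) {
    dm <- .dummy_columns(base[[f]][bidx], f)
    for (j in seq_len(ncol(dm))) push(dm[, j], colnames(dm)[j], "indicator")
  }
  push(as.numeric(fu$wave == 2), "wave2", "wave")
  push(as.numeric(fu$wave == 3), "wave3", "wave")

  if (set %in% c("demographic+function", "full")) {
    for (s in FUNCTION_SCALES) {
      push(base[[s]][bidx], paste0(s, "_baseline"), "baseline")
      push(ch[[paste0(s, "_change")]], paste0(s, "_change"), "change")
    }
    push(as.numeric(fu$has_drive), "has_drive", "indicator")
    push(as.numeric(fu$has_ride), "has_ride", "indicator")
    push(as.numeric(fu$has_wheelchair), "has_wheelchair", "indicator")
  }
  if (set %in% c("demographic+medical", "full")) {
    for (m in med_vars) {
      push(base[[m]][bidx], paste0(m, "_baseline"), "baseline")
      push(ch[[paste0(m, "_change")]], paste0(m, "_change"), "change")
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  kinds_std <- ifelse(kinds %in% c("indicator", "wave"), "indicator", kinds)
  if (is.null(scaling)) scaling <- fit_scaling(X, kinds_std)
  Xs <- standardize(X, scaling)
  mask <- !is.na(Xs)

  structure(
    list(
      X = Xs, mask = mask, y = as.integer(fu$steady_work),
      participant = fu$participant_id, wave = fu$wave,
      column_kind = kinds, scaling = scaling, predictor_set = set,
      m_max = m_max, n_dropped = n_dropped
    ),
    class = "sw_design"
  )
}

#' @export
print.sw_design <- function(x, ...) {
  cat("<sw_design> ", nrow(x$X), " observations x ", ncol(x$X), " columns (",
      x$predictor_set, ", m_max = ", x$m_max, ")\n", sep = "")
  cat("  participants: ", length(unique(x$participant)),
      " (", x$n_dropped, " dropped by filter)\n", sep = "")
  cat("  outcome rate: ", round(mean(x$y), 3),
      "; missing cells: ", sum(!x$mask), "\n", sep = "")
  invisible(x)
}

#' Export a standardized design as CSV plus a JSON sidecar
#'
#' The CSV holds the standardized matrix (empty cell = missing) together
#' with the outcome, participant, and wave; the sidecar records the scaling
#' parameters, column kinds, and predictor set.
#'
#' @param design An `sw_design`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  df <- data.frame(participant_id = design$participant, wave = design$wave,
                   steady_work = design$y)
  df <- cbind(df, as.data.frame(design$X))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(
      predictor_set = design$predictor_set, m_max = design$m_max,
      column_kind = as.list(design$column_kind),
      scaling = list(center = as.list(design$scaling$center),
                     scale = as.list(design$scaling$scale))
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
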