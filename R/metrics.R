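# ROC and precision-recall curves from LOO predictive probabilities, and
# the cross-model comparison table.

.score_outcome <- function(scores, outcomes) {
  if (inherits(scores, "sw_loo")) {
    if (is.null(outcomes)) outcomes <- attr(scores, "y")
    scores <- scores$prob
  }
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes differ in length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(outcomes)) stop("missing scores or outcomes", call. = FALSE)
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary", call. = FALSE)
  list(s = as.numeric(scores), y = as.integer(outcomes))
}

#' Receiver operating characteristic curve and AUROC
#'
#' Sweeps a decision threshold over the unique scores (tied scores grouped
#' at a single threshold), traces (FPR, TPR) from (0, 0) to (1, 1), and
#' computes the area by the trapezoidal rule (equivalently, the
#' Mann-Whitney probability with ties counted one-half).
#'
#' @param scores Numeric predictive scores, or an `sw_loo`.
#' @param outcomes Binary outcomes (taken from the `sw_loo` if omitted).
#' @return An object of class `sw_curve`: list with `points` (data frame
#'   `fpr`, `tpr`, `threshold`), `auc`, `type = "roc"`.
#' @export
roc_curve <- function(scores, outcomes = NULL) {
  so <- .score_outcome(scores, outcomes)
  npos <- sum(so$y == 1L); nneg <- sum(so$y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  ord <- order(so$s, decreasing = TRUE)
  s <- so$s[ord]; y <- so$y[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE)) # last index of each tie group
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1L - y)[grp_last]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  thr <- c(Inf, s[grp_last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc, type = "roc"),
            class = "sw_curve")
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every threshold over the unique scores; the area
#' is the average-precision step convention
#' `sum_k (R_k - R_{k-1}) P_k` (no optimistic linear interpolation).
#' With all scores tied the curve is the single point
#' (recall 1, precision = prevalence).
#'
#' @inheritParams roc_curve
#' @return An `sw_curve` with `points` (`recall`, `precision`,
#'   `threshold`), `auc` (average precision), `type = "pr"`.
#' @export
pr_curve <- function(scores, outcomes = NULL) {
  so <- .score_outcome(scores, outcomes)
  npos <- sum(so$y == 1L)
  if (npos == 0L) stop("no positive outcomes", call. = FALSE)
  ord <- order(so$s, decreasing = TRUE)
  s <- so$s[ord]; y <- so$y[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[grp_last]
  npred <- grp_last
  precision <- tp / npred
  recall <- tp / npos
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(recall = recall, precision = precision,
                                     threshold = s[grp_last]),
                 auc = ap, type = "pr"),
            class = "sw_curve")
}

#' @export
print.sw_curve <- function(x, ...) {
  cat("<sw_curve> ", toupper(x$type), ": area = ", round(x$auc, 4),
      " (", nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' @export
plot.sw_curve <- function(x, ...) {
  if (x$type == "roc") {
    graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (AUROC = %.3f)", x$auc), ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    graphics::plot(x$points$recall, x$points$precision, type = "s",
                   xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
                   main = sprintf("Precision-recall (area = %.3f)", x$auc), ...)
  }
  invisible(x)
}

#' Compare models on identical observations by LOO AUROC and PR area
#'
#' @param runs Named list of `sw_loo` objects, all evaluated on the
#'   identical observation set (checked; never silently intersected).
#' @return An object of class `sw_comparison`: data frame with one row per
#'   run (`model`, `family`, `predictor_set`, `auroc`, `pr_area`, `elpd`,
#'   `n_obs`, `n_high_k`), sorted by AUROC, best first.
#' @export
compare_models <- function(runs) {
  if (!length(runs) || is.null(names(runs)) || any(names(runs) == "")) {
    stop("runs must be a non-empty named list", call. = FALSE)
  }
  ys <- lapply(runs, attr, "y")
  for (i in seq_along(ys)) {
    if (!identical(ys[[i]], ys[[1L]])) {
      stop("runs were evaluated on different observation sets: ",
           names(runs)[i], call. = FALSE)
    }
  }
  rows <- lapply(names(runs), function(nm) {
    lo <- runs[[nm]]
    data.frame(
      model = nm,
      family = attr(lo, "family") %||% NA_character_,
      predictor_set = attr(lo, "predictor_set") %||% NA_character_,
      auroc = roc_curve(lo)$auc,
      pr_area = pr_curve(lo)$auc,
      elpd = attr(lo, "elpd"),
      n_obs = nrow(lo),
      n_high_k = sum(lo$pareto_k > 0.7, na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auroc), ]
  rownames(out) <- NULL
  class(out) <- c("sw_comparison", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
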