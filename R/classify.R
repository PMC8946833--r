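# Positivity classification. One threshold is derived from the untreated
# control of an experiment and reused, unchanged, for every image of that
# experiment; a cell is gamma-H2AX positive when its per-cell maximum
# signal strictly exceeds the threshold.

#' Derive an experiment's positivity threshold from its untreated control
#'
#' Methods on the control cells' `max_signal` distribution:
#' \describe{
#'   \item{`mean_k_sd`}{mean + k standard deviations (default k = 2), the
#'     standard control-anchored positivity rule.}
#'   \item{`percentile`}{the p-th percentile (linear interpolation,
#'     [stats::quantile()] type 7; default p = 99).}
#'   \item{`otsu_on_scores`}{the between-class-variance-maximizing split of
#'     the score distribution; appropriate when the control is visibly
#'     bimodal.}
#'   \item{`fixed`}{a user-supplied value, ignoring the data.}
#' }
#'
#' @param control_cells `CellTable` of the experiment's untreated control
#'   cells (non-empty).
#' @param method One of `"mean_k_sd"`, `"percentile"`, `"otsu_on_scores"`,
#'   `"fixed"`.
#' @param method_params Named list: `k` for `mean_k_sd`, `p` (percent) for
#'   `percentile`, `value` for `fixed`.
#' @param experiment Experiment identifier; defaults to the control table's.
#' @return An `experiment_threshold`: `experiment`, `threshold`, `method`,
#'   `method_params`, `source_condition` (arm, treatment), `n_control_cells`.
#' @export
derive_threshold <- function(control_cells,
                             method = c("mean_k_sd", "percentile",
                                        "otsu_on_scores", "fixed"),
                             method_params = list(),
                             experiment = NULL) {
  method <- match.arg(method)
  if (method != "fixed") {
    if (is.null(control_cells) || nrow(control_cells) == 0) {
      stop("cannot derive a threshold: the untreated control has no cells")
    }
  }
  x <- control_cells$max_signal
  thr <- switch(method,
    mean_k_sd = {
      k <- method_params$k %||% 2
      s <- if (length(x) > 1) sd(x) else 0
      mean(x) + k * s
    },
    percentile = {
      p <- method_params$p %||% 99
      as.numeric(quantile(x, probs = p / 100, type = 7, names = FALSE))
    },
    otsu_on_scores = otsu_scores(x),
    fixed = {
      if (is.null(method_params$value)) stop("fixed method needs $value")
      method_params$value
    }
  )
  if (!is.finite(thr) || thr < 0) {
    stop("derived threshold is not a finite non-negative number: ", thr)
  }
  if (is.null(experiment)) {
    experiment <- unique(control_cells$experiment)
    if (length(experiment) != 1) experiment <- NA_character_
  }
  src <- c(arm = as.character(unique(control_cells$arm)[1]),
           treatment = as.character(unique(control_cells$treatment)[1]))
  structure(
    list(experiment = experiment, threshold = thr, method = method,
         method_params = method_params, source_condition = src,
         n_control_cells = if (is.null(control_cells)) 0L
                           else nrow(control_cells)),
    class = "experiment_threshold"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Otsu's method on a 1-D score sample: exhaustive search over midpoints
# between consecutive sorted unique values, maximizing between-class
# variance w1*w2*(m1-m2)^2.
otsu_scores <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(u[1])
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(x)
  xs <- sort(x)
  cs <- cumsum(xs)
  # for each candidate, number of values <= candidate
  k <- findInterval(cand, xs)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bcv <- (k / n) * ((n - k) / n) * (m1 - m2)^2
  cand[which.max(bcv)]
}

#' @export
print.experiment_threshold <- function(x, ...) {
  cat("<experiment_threshold> experiment=", x$experiment,
      " threshold=", signif(x$threshold, 6),
      " method=", x$method, "\n", sep = "")
  invisible(x)
}

#' Count gamma-H2AX-positive cells under an experiment threshold
#'
#' A cell is positive when `max_signal > threshold` (strict: a score equal
#' to the threshold is negative). Cells from all fields of a condition are
#' pooled; per-field summaries can be obtained by grouping beforehand.
#'
#' @param cells `CellTable` of one condition (one experiment, arm,
#'   treatment; any number of fields).
#' @param threshold An `experiment_threshold` from [derive_threshold()], or
#'   a bare number.
#' @param check_experiment Verify that the cells belong to the threshold's
#'   experiment (default `TRUE` when an `experiment_threshold` is given).
#' @return A `PositivitySummary` data frame (one row): `experiment`, `arm`,
#'   `treatment`, `n_cells`, `n_positive`, `pct_positive`, `threshold`.
#'   `pct_positive` is `NA` (flagged) when `n_cells` is 0.
#' @export
count_positive <- function(cells, threshold, check_experiment = TRUE) {
  if (inherits(threshold, "experiment_threshold")) {
    thr <- threshold$threshold
    if (check_experiment && nrow(cells) > 0) {
      exps <- unique(cells$experiment)
      if (!all(is.na(exps)) && !is.na(threshold$experiment) &&
          !all(exps == threshold$experiment)) {
        stop("cells belong to experiment(s) ",
             paste(exps, collapse = ", "),
             " but the threshold was derived for ", threshold$experiment)
      }
    }
  } else {
    thr <- threshold
  }
  one <- function(v) if (length(v) == 0 || all(is.na(v))) NA else unique(v)[1]
  n <- nrow(cells)
  npos <- if (n > 0) sum(cells$max_signal > thr) else 0L
  data.frame(
    experiment = one(cells$experiment), arm = one(cells$arm),
    treatment = one(cells$treatment),
    n_cells = n, n_positive = npos,
    pct_positive = if (n > 0) 100 * npos / n else NA_real_,
    threshold = thr,
    stringsAsFactors = FALSE
  )
}
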