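# Co-stress statistics: treated-vs-untreated fold changes of the percent
# of gamma-H2AX-positive cells within each pre-stress arm, iterated Grubbs
# outlier exclusion, normality testing, and paired t-tests across
# replicate experiments.

#' Fold change of percent-positive cells, treated vs untreated
#'
#' @param treated,untreated Single-row `PositivitySummary` data frames
#'   (see [count_positive()]) from the same experiment and arm.
#' @return A `FoldChangeResult` data frame (one row): `experiment`, `arm`,
#'   `treatment`, `fc`, `treated_pct`, `untreated_pct`, `undefined`,
#'   `reason`. When the untreated percentage is 0 (or either side is
#'   missing) the result is flagged `undefined` with `fc = NA` and a
#'   reason, for exclusion downstream.
#' @export
fold_change <- function(treated, untreated) {
  stopifnot(nrow(treated) == 1, nrow(untreated) == 1)
  same <- function(col) {
    isTRUE(treated[[col]] == untreated[[col]]) ||
      (is.na(treated[[col]]) && is.na(untreated[[col]]))
  }
  if (!same("experiment") || !same("arm")) {
    stop("fold_change requires summaries from the same experiment and arm")
  }
  tp <- treated$pct_positive
  up <- untreated$pct_positive
  undefined <- FALSE
  reason <- NA_character_
  fc <- NA_real_
  if (is.na(tp) || is.na(up)) {
    undefined <- TRUE
    reason <- "missing percent-positive (condition with zero cells)"
  } else if (up == 0) {
    undefined <- TRUE
    reason <- "untreated percent-positive is 0; ratio undefined"
  } else {
    fc <- tp / up
  }
  data.frame(
    experiment = treated$experiment, arm = treated$arm,
    treatment = treated$treatment,
    fc = fc, treated_pct = tp, untreated_pct = up,
    undefined = undefined, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' All treated-vs-untreated fold changes in a positivity table
#'
#' @param positivity `PositivitySummary` data frame with one row per
#'   (experiment, arm, treatment); must contain an `untreated` row for
#'   every (experiment, arm) with treated rows.
#' @param untreated_label Treatment label of the untreated condition.
#' @return A `FoldChangeResult` data frame, one row per treated condition.
#' @export
compute_fold_changes <- function(positivity, untreated_label = "untreated") {
  out <- list()
  groups <- unique(positivity[, c("experiment", "arm")])
  for (g in seq_len(nrow(groups))) {
    sub <- positivity[positivity$experiment == groups$experiment[g] &
                      positivity$arm == groups$arm[g], , drop = FALSE]
    untr <- sub[sub$treatment == untreated_label, , drop = FALSE]
    if (nrow(untr) != 1) {
      stop("experiment ", groups$experiment[g], ", arm ", groups$arm[g],
           " needs exactly one '", untreated_label, "' row, found ",
           nrow(untr))
    }
    for (tr in setdiff(sub$treatment, untreated_label)) {
      out[[length(out) + 1L]] <-
        fold_change(sub[sub$treatment == tr, , drop = FALSE], untr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Closed-form two-sided Grubbs critical value:
# G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2)),
# t the upper alpha/(2n) quantile of Student's t with n-2 df.
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterated two-sided Grubbs outlier exclusion
#'
#' Repeatedly tests the most extreme value: `G = max|x_i - mean| / sd`
#' against the closed-form critical value; while `G` exceeds it, the
#' extreme point is removed and the reduced sample re-tested. Iteration
#' stops when `G` is no longer significant or fewer than 3 values remain,
#' so at most `n - 3` points can ever be excluded.
#'
#' @param values Numeric vector of finite values.
#' @param alpha Significance level (default 0.05).
#' @return A `grubbs_result` list: `values`, `alpha`, `excluded_indices`
#'   (positions in the input, in exclusion order), `g_statistics` and
#'   `critical_values` (one per iteration, including the final
#'   non-significant one), `kept` (logical mask), `kept_values`.
#'   With `n < 3` no test is run (warning) and nothing is excluded; a
#'   zero-variance sample leaves `G` undefined and excludes nothing.
#' @export
grubbs_exclude <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), all(is.finite(values)),
            alpha > 0, alpha < 1)
  idx <- seq_along(values)
  excluded <- integer(0)
  gs <- numeric(0)
  crits <- numeric(0)
  if (length(values) < 3) {
    warning("Grubbs test needs at least 3 values; none excluded")
  } else {
    repeat {
      x <- values[setdiff(idx, excluded)]
      n <- length(x)
      if (n < 3) break
      s <- sd(x)
      if (s == 0) break
      dev <- abs(x - mean(x))
      g <- max(dev) / s
      crit <- grubbs_critical(n, alpha)
      gs <- c(gs, g)
      crits <- c(crits, crit)
      if (g <= crit) break
      worst_local <- which.max(dev)
      excluded <- c(excluded, setdiff(idx, excluded)[worst_local])
    }
  }
  kept <- !(idx %in% excluded)
  structure(
    list(values = values, alpha = alpha, excluded_indices = excluded,
         g_statistics = gs, critical_values = crits,
         kept = kept, kept_values = values[kept]),
    class = "grubbs_result"
  )
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat("<grubbs_result> n=", length(x$values), ", excluded=",
      length(x$excluded_indices),
      if (length(x$excluded_indices))
        paste0(" (", paste(signif(x$values[x$excluded_indices], 4),
                           collapse = ", "), ")") else "",
      ", alpha=", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] that flags (rather than
#' errors on) zero-variance samples and, when `warn = TRUE`, emits a
#' warning when normality is rejected at `alpha` -- the convention used
#' before the pipeline's paired t-tests.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Level used for the warning.
#' @param warn Warn when `p < alpha`.
#' @return List: `w`, `p`, `degenerate` (zero variance), `n`.
#' @export
normality_test <- function(values, alpha = 0.05, warn = FALSE) {
  if (length(values) < 3) {
    stop("normality test needs at least 3 values, got ", length(values))
  }
  if (sd(values) == 0) {
    warning("zero-variance sample; normality test is degenerate")
    return(list(w = NA_real_, p = NA_real_, degenerate = TRUE,
                n = length(values)))
  }
  st <- shapiro.test(values)
  if (warn && st$p.value < alpha) {
    warning("normality rejected (Shapiro-Wilk p = ",
            signif(st$p.value, 3), "); t-test proceeds regardless")
  }
  list(w = unname(st$statistic), p = st$p.value, degenerate = FALSE,
       n = length(values))
}

#' Paired t-test with normality check
#'
#' Two-sided paired t-test on `x - y` via [stats::t.test()], preceded by a
#' Shapiro-Wilk test of the paired differences (recorded; a warning, not
#' an abort, when rejected). Zero-variance differences yield a flagged
#' degenerate result instead of an error.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 2`.
#' @param alpha Level for the normality warning.
#' @return A `paired_test_result` list: `t_statistic`, `df`, `p_value`,
#'   `normality_w`, `normality_p`, `n_pairs`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  nw <- np <- NA_real_
  if (length(d) >= 3 && sd(d) > 0) {
    ns <- normality_test(d, alpha = alpha, warn = TRUE)
    nw <- ns$w; np <- ns$p
  }
  if (sd(d) == 0) {
    return(structure(
      list(t_statistic = NA_real_, df = length(d) - 1L, p_value = NA_real_,
           normality_w = nw, normality_p = np, n_pairs = length(d),
           mean_difference = mean(d), degenerate = TRUE),
      class = "paired_test_result"
    ))
  }
  tt <- t.test(x, y, paired = TRUE)
  structure(
    list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, normality_w = nw, normality_p = np,
         n_pairs = length(d), mean_difference = mean(d), degenerate = FALSE),
    class = "paired_test_result"
  )
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat("<paired_test_result> t=", signif(x$t_statistic, 5),
      ", df=", x$df, ", p=", signif(x$p_value, 4),
      ", n=", x$n_pairs,
      if (isTRUE(x$degenerate)) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Compare pre-stress arms by paired t-tests on fold changes
#'
#' For each treatment, pairs the two arms' fold changes by experiment,
#' optionally applies iterated Grubbs exclusion to the paired differences
#' (excluding whole pairs), and runs a two-sided paired t-test. Undefined
#' fold changes are dropped (with their pair) beforehand.
#'
#' @param fc `FoldChangeResult` data frame from [compute_fold_changes()],
#'   covering two arms.
#' @param arms Character vector of length 2, compared as `arms[1]` minus
#'   `arms[2]`.
#' @param alpha Significance level for the Grubbs exclusion and normality
#'   warning.
#' @param grubbs Apply Grubbs exclusion to the paired differences.
#' @return Data frame, one row per treatment: `treatment`, `n_pairs`,
#'   `mean_fc_arm1`, `mean_fc_arm2`, `t_statistic`, `df`, `p_value`,
#'   `normality_w`, `normality_p`, `n_excluded`.
#' @export
compare_arms <- function(fc, arms = c("control", "osmotic"), alpha = 0.05,
                         grubbs = TRUE) {
  stopifnot(length(arms) == 2)
  fc <- fc[!fc$undefined, , drop = FALSE]
  out <- list()
  for (tr in unique(fc$treatment)) {
    a <- fc[fc$treatment == tr & fc$arm == arms[1], c("experiment", "fc")]
    b <- fc[fc$treatment == tr & fc$arm == arms[2], c("experiment", "fc")]
    m <- merge(a, b, by = "experiment", suffixes = c("_1", "_2"))
    if (nrow(m) < 2) {
      warning("treatment ", tr, ": fewer than 2 complete pairs; skipped")
      next
    }
    x <- m$fc_1; y <- m$fc_2
    n_excl <- 0L
    if (grubbs && length(x) >= 3) {
      gr <- grubbs_exclude(x - y, alpha = alpha)
      n_excl <- length(gr$excluded_indices)
      x <- x[gr$kept]; y <- y[gr$kept]
    }
    tt <- paired_t_test(x, y, alpha = alpha)
    out[[tr]] <- data.frame(
      treatment = tr, n_pairs = tt$n_pairs,
      mean_fc_arm1 = mean(x), mean_fc_arm2 = mean(y),
      t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
      normality_w = tt$normality_w, normality_p = tt$normality_p,
      n_excluded = n_excl, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
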