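make_summary <- function(pct, experiment = "e1", arm = "control",
                         treatment = "UV") {
  data.frame(experiment = experiment, arm = arm, treatment = treatment,
             n_cells = 1000L, n_positive = round(10 * pct),
             pct_positive = pct, threshold = 100,
             stringsAsFactors = FALSE)
}

test_that("fold change is the ratio of percent-positive values", {
  fc <- fold_change(make_summary(24), make_summary(10,
                                                   treatment = "untreated"))
  expect_equal(fc$fc, 2.4)
  same <- fold_change(make_summary(13), make_summary(13,
                                                     treatment = "untreated"))
  expect_equal(same$fc, 1)
  expect_error(fold_change(make_summary(24),
                           make_summary(10, arm = "osmotic")),
               "same experiment and arm")
})

test_that("a zero untreated percentage flags the fold change as undefined", {
  fc <- fold_change(make_summary(24), make_summary(0,
                                                   treatment = "untreated"))
  expect_true(fc$undefined)
  expect_true(is.na(fc$fc))
  expect_match(fc$reason, "untreated")
})

test_that("compute_fold_changes emits one ratio per treated condition", {
  pos <- rbind(
    make_summary(10, treatment = "untreated"),
    make_summary(24, treatment = "UV"),
    make_summary(47, treatment = "H2O2"),
    make_summary(10, arm = "osmotic", treatment = "untreated"),
    make_summary(12, arm = "osmotic", treatment = "UV"),
    make_summary(19, arm = "osmotic", treatment = "H2O2")
  )
  fc <- compute_fold_changes(pos)
  expect_equal(nrow(fc), 4)
  expect_equal(fc$fc[fc$arm == "control" & fc$treatment == "UV"], 2.4)
  expect_equal(fc$fc[fc$arm == "osmotic" & fc$treatment == "H2O2"], 1.9)
})

test_that("Grubbs critical values follow the t-quantile closed form", {
  for (n in c(3, 4, 6, 10, 30)) {
    t <- qt(0.05 / (2 * n), n - 2, lower.tail = FALSE)
    expected <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
    expect_equal(gammahq:::grubbs_critical(n, 0.05), expected,
                 tolerance = 1e-12)
  }
  # published reference value for n = 10, alpha = 0.05 (two-sided)
  expect_equal(gammahq:::grubbs_critical(10, 0.05), 2.29, tolerance = 0.005)
})

test_that("the worked Grubbs example excludes exactly the aberrant point", {
  g <- grubbs_exclude(c(8, 9, 10, 50), alpha = 0.05)
  expect_equal(g$excluded_indices, 4L)
  # hand-computed: mean 19.25, sd 20.516, G = 30.75 / 20.516 = 1.4988 > 1.4812
  expect_equal(g$g_statistics[1], 1.4988, tolerance = 1e-3)
  expect_equal(g$critical_values[1], 1.4812, tolerance = 1e-3)
  # after exclusion {8,9,10}: G = 1 < 1.1531, iteration stops
  expect_equal(g$g_statistics[2], 1, tolerance = 1e-6)
  expect_equal(g$critical_values[2], 1.1543, tolerance = 1e-3)
  expect_equal(g$kept_values, c(8, 9, 10))
})

test_that("Grubbs degenerate cases exclude nothing", {
  expect_equal(grubbs_exclude(c(5, 5, 5, 5))$excluded_indices, integer(0))
  expect_equal(grubbs_exclude(c(1, 2, 3))$excluded_indices, integer(0))
  expect_warning(g <- grubbs_exclude(c(1, 100)), "at least 3")
  expect_equal(g$excluded_indices, integer(0))
})

test_that("Grubbs iteration never reduces a sample below 3 values", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(4), rnorm(4, 0, 1e-3) + c(50, -80, 120, 200))
    g <- grubbs_exclude(x)
    expect_lte(length(g$excluded_indices), length(x) - 3)
    expect_gte(sum(g$kept), 3)
  }
})

test_that("the normality test is calibrated and has power", {
  ok <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    if (normality_test(rnorm(200))$p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.85)

  rejected <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    if (normality_test(rexp(50))$p < 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected / 40, 0.9)

  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_warning(r <- normality_test(rep(2, 10)), "zero-variance")
  expect_true(r$degenerate)
})

test_that("the paired t-test matches the closed form on the worked example", {
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  # d = {1,2,3}: t = 2 / (1 / sqrt(3)) = 3.4641, df = 2
  expect_equal(r$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(3.4641, 2, lower.tail = FALSE),
               tolerance = 1e-4)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
})

test_that("the paired t-test is antisymmetric and flags degenerate input", {
  set.seed(7)
  x <- rnorm(6); y <- rnorm(6)
  a <- paired_t_test(x, y)
  b <- paired_t_test(y, x)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)

  d <- paired_t_test(x, x)
  expect_true(d$degenerate)

  # constant shift with tiny jitter: overwhelming evidence
  set.seed(8)
  y2 <- x + 5 + rnorm(6, 0, 1e-4)
  expect_lt(paired_t_test(y2, x)$p_value, 0.001)
})

test_that("arm comparison detects the blunted osmotic response", {
  set.seed(41)
  fcs <- list()
  for (ex in 1:6) {
    fcs[[ex]] <- data.frame(
      experiment = paste0("e", ex),
      arm = rep(c("control", "osmotic"), each = 2),
      treatment = rep(c("UV", "H2O2"), 2),
      fc = c(2.4, 4.7, 1.2, 1.9) + rnorm(4, 0, 0.2),
      undefined = FALSE, stringsAsFactors = FALSE
    )
  }
  res <- compare_arms(do.call(rbind, fcs))
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(res$mean_fc_arm1 > res$mean_fc_arm2))
})

test_that("Grubbs exclusion inside the arm comparison removes a wild pair", {
  set.seed(5)
  fcs <- do.call(rbind, lapply(1:7, function(ex) data.frame(
    experiment = paste0("e", ex), arm = c("control", "osmotic"),
    treatment = "UV", fc = c(2.4, 1.2) + rnorm(2, 0, 0.1),
    undefined = FALSE, stringsAsFactors = FALSE)))
  fcs$fc[fcs$experiment == "e7" & fcs$arm == "control"] <- 40
  res <- compare_arms(fcs)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$n_pairs, 6L)
})
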