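test_that("an empty field is pure background plus gradient and noise", {
  p <- small_field_params(n_cells = 0, noise_sd = 0,
                          background_gradient_amplitude = 0, rng_seed = 1)
  f <- generate_field(p)
  expect_equal(nrow(f$truth$cells), 0)
  expect_true(all(f$pair$dapi == p$background_level))
  expect_true(all(f$pair$signal == p$background_level))

  p2 <- small_field_params(n_cells = 0, noise_sd = 0,
                           background_gradient_amplitude = 50, rng_seed = 1)
  f2 <- generate_field(p2)
  expect_equal(max(f2$pair$dapi) - min(f2$pair$dapi), 50)
})

test_that("a noise-free field has exactly n_cells DAPI components (flood-fill oracle)", {
  p <- small_field_params(n_cells = 5, noise_sd = 0,
                          background_gradient_amplitude = 0, rng_seed = 3)
  f <- generate_field(p)
  mask <- f$pair$dapi > p$background_level + 1
  expect_equal(flood_fill_count(mask, 8L), 5L)
})

test_that("degenerate positive fractions are honored", {
  f1 <- generate_field(small_field_params(positive_fraction = 1, rng_seed = 2))
  expect_true(all(f1$truth$cells$is_positive))
  expect_equal(f1$truth$true_positive_fraction, 1)
  f0 <- generate_field(small_field_params(positive_fraction = 0, rng_seed = 2))
  expect_false(any(f0$truth$cells$is_positive))
})

test_that("identical seeds give bit-identical fields", {
  p <- small_field_params(rng_seed = 11)
  a <- generate_field(p)
  b <- generate_field(p)
  expect_identical(a$pair$dapi, b$pair$dapi)
  expect_identical(a$pair$signal, b$pair$signal)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("infeasible placement errors and names the achievable count", {
  p <- small_field_params(n_cells = 200, min_center_separation = 60,
                          rng_seed = 1)
  expect_error(generate_field(p), "could only place")
  expect_error(generate_field(sim_field_params(bit_depth = 12)),
               "bit_depth")
})

test_that("separation guarantee: generated nuclei disks never overlap", {
  for (seed in 1:8) {
    p <- small_field_params(n_cells = 8, rng_seed = seed)
    # min separation 28 > 2 * (7 + 3 * 0.8) = 18.8
    tc <- generate_field(p)$truth$cells
    d <- as.matrix(dist(tc[, c("row", "col")]))
    rsum <- outer(tc$radius, tc$radius, "+")
    diag(d) <- Inf
    expect_true(all(d > rsum))
  }
})

test_that("experiment layout applies configured per-condition fractions", {
  params <- sim_experiment_params(
    baseline_positive_fraction = 0.10,
    n_fields_per_condition = 1,
    field_params = small_field_params(),
    rng_seed = 5
  )
  exp <- generate_experiment(params)
  man <- exp$manifest
  expect_equal(nrow(man), 6)  # 2 arms x 3 treatments x 1 field
  expect_equal(man$configured_fraction[man$arm == "control" &
                                       man$treatment == "UV"], 0.24)
  expect_equal(man$configured_fraction[man$arm == "osmotic" &
                                       man$treatment == "H2O2"], 0.19)
  expect_equal(man$configured_fraction[man$treatment == "untreated"],
               c(0.1, 0.1))
})

test_that("a factor pushing the fraction past 1 clamps with a warning", {
  params <- sim_experiment_params(
    baseline_positive_fraction = 0.25,
    arm_effects = costress_arm_effects(control_h2o2 = 4.7),
    n_fields_per_condition = 1,
    field_params = small_field_params(), rng_seed = 1
  )
  expect_warning(exp <- generate_experiment(params), "clamped")
  man <- exp$manifest
  expect_equal(man$configured_fraction[man$arm == "control" &
                                       man$treatment == "H2O2"], 1)
})

test_that("pooled realized positive fraction is binomial around the configured one", {
  one_arm <- data.frame(arm = "control", treatment = "untreated", factor = 1)
  params <- sim_experiment_params(
    baseline_positive_fraction = 0.10, arm_effects = one_arm,
    n_fields_per_condition = 60,
    field_params = small_field_params(n_cells = 40,
                                      min_center_separation = 18),
    rng_seed = 9
  )
  exp <- generate_experiment(params)
  labels <- unlist(lapply(exp$fields, function(f) f$truth$cells$is_positive))
  n_total <- length(labels)
  expect_equal(n_total, 60 * 40)
  se <- sqrt(0.1 * 0.9 / n_total)
  expect_lt(abs(mean(labels) - 0.10), 3 * se)
})

test_that("experiments are reproducible from their seed", {
  params <- sim_experiment_params(field_params = small_field_params(),
                                  n_fields_per_condition = 1, rng_seed = 21)
  a <- generate_experiment(params)
  b <- generate_experiment(params)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$fields, function(f) f$pair$signal),
                   lapply(b$fields, function(f) f$pair$signal))
})

test_that("noise-free Cq tables invert the ddCt model exactly", {
  p <- sim_qpcr_params(cq_noise_sd = 0, rng_seed = 1,
                       true_log2_fc = c(ATM = -1, ATR = -0.8,
                                        PP4 = 1, CCDC6 = -1.5))
  tab <- generate_qpcr_table(p)
  res <- analyze_qpcr(tab, reference_gene = "18S", apply_grubbs = FALSE)
  expect_equal(res$log2_fc[res$gene == "ATM"], -1)
  expect_equal(res$fold_change[res$gene == "ATM"], 0.5)
  # reference gene independent of condition
  ref <- tab[tab$gene == "18S", ]
  expect_equal(unique(ref$cq), p$reference_cq_mean)
})

test_that("noisy Cq tables recover log2 fold changes within propagated error", {
  p <- sim_qpcr_params(genes = "ATM", true_log2_fc = c(ATM = -1),
                       n_replicates = 8, cq_noise_sd = 0.2, rng_seed = 17)
  tab <- generate_qpcr_table(p)
  res <- analyze_qpcr(tab, apply_grubbs = FALSE)
  # var(ddct_hat) = 2 * (2 * sd^2) / n  => sd = cq_noise_sd * sqrt(4 / n)
  tol <- 3 * 0.2 * sqrt(4 / 8)
  expect_lt(abs(res$log2_fc - (-1)), tol)
})
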