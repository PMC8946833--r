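test_that("background subtraction removes constant and preserves identity", {
  u <- matrix(7, 64, 64)
  expect_true(all(subtract_background(u, "median", 5) == 0))
  expect_true(all(subtract_background(u, "rolling_ball", 5) == 0))
  expect_identical(subtract_background(u, "none"), u)
  expect_error(subtract_background(u, "rolling_ball", 40), "too large")
  expect_true(all(subtract_background(u, "rolling_ball", 5) >= 0))
})

test_that("rolling-ball subtraction preserves a disk's excess over a ramp", {
  h <- w <- 120
  ramp <- outer(seq_len(h), seq_len(w),
                function(r, c) 50 + 0.4 * r + 0.2 * c)
  img <- ramp
  disk <- outer(seq_len(h), seq_len(w),
                function(r, c) (r - 60)^2 + (c - 60)^2 <= 36)
  img[disk] <- img[disk] + 500
  corr <- subtract_background(img, "rolling_ball", 25)
  # excess over the known local ramp, compared analytically
  expect_true(all(corr[disk] >= 0.9 * 500))
  expect_true(all(corr[disk] <= 500 + 25))
  expect_true(mean(corr[!disk]) < 15)
})

test_that("segmentation finds every simulated nucleus in a clean field", {
  p <- small_field_params(n_cells = 5, noise_sd = 0,
                          background_gradient_amplitude = 0, rng_seed = 3)
  f <- generate_field(p)
  lm <- segment_nuclei(f$pair$dapi, small_seg_params())
  expect_equal(lm$n_labels, 5L)
  # labels consecutive, shape preserved, pairwise disjoint by construction
  expect_setequal(unique(as.vector(lm$labels)), 0:5)
  expect_equal(dim(lm$labels), dim(f$pair$dapi))
})

test_that("an all-background image yields an empty label map, not an error", {
  lm <- segment_nuclei(matrix(0, 64, 64), small_seg_params())
  expect_equal(lm$n_labels, 0L)
  lm2 <- segment_nuclei(matrix(100, 64, 64), small_seg_params())
  expect_equal(lm2$n_labels, 0L)
})

test_that("watershed splitting separates two merged disks", {
  h <- w <- 80
  img <- matrix(0, h, w)
  # two disks of radius 10 with centers 16 px apart: one 4-connected blob
  for (ctr in list(c(40, 32), c(40, 48))) {
    d <- outer(seq_len(h), seq_len(w),
               function(r, c) (r - ctr[1])^2 + (c - ctr[2])^2 <= 100)
    img[d] <- 1000
  }
  merged <- segment_nuclei(img, segmentation_params(
    background_method = "none", dapi_threshold_method = "fixed",
    fixed_threshold = 500, min_area = 10, exclude_border = FALSE,
    split_touching = FALSE))
  expect_equal(merged$n_labels, 1L)
  split <- segment_nuclei(img, segmentation_params(
    background_method = "none", dapi_threshold_method = "fixed",
    fixed_threshold = 500, min_area = 10, exclude_border = FALSE,
    split_touching = TRUE))
  expect_equal(split$n_labels, 2L)
})

test_that("connectivity setting changes diagonal-touching components", {
  m <- matrix(0, 10, 10)
  m[2, 2] <- 1; m[3, 3] <- 1  # touch only diagonally
  lm8 <- gammahq:::label_components(m > 0, 8L)
  lm4 <- gammahq:::label_components(m > 0, 4L)
  expect_equal(lm8$n_labels, 1L)
  expect_equal(lm4$n_labels, 2L)
  expect_equal(lm8$n_labels, flood_fill_count(m > 0, 8L))
  expect_equal(lm4$n_labels, flood_fill_count(m > 0, 4L))
})

test_that("label filtering respects area bounds, border contact and monotonicity", {
  lab <- matrix(0L, 40, 40)
  lab[2:3, 2:6] <- 1L            # area 10, interior
  lab[10:14, 10:19] <- 2L        # area 50, interior
  lab[20:40, 20:40] <- 3L        # area 441, touches the border
  lm <- gammahq:::new_label_map(lab, 3L)

  out <- filter_labels(lm, min_area = 20, max_area = 100)
  expect_equal(out$n_labels, 1L)
  expect_equal(sum(out$labels == 1L), 50)

  expect_equal(filter_labels(lm, min_area = 1)$n_labels, 3L)
  expect_equal(filter_labels(lm, min_area = 1000)$n_labels, 0L)
  expect_equal(filter_labels(lm, min_area = 1,
                             exclude_border = TRUE)$n_labels, 2L)

  counts <- vapply(c(1, 10, 11, 50, 51, 441, 442),
                   function(a) filter_labels(lm, min_area = a)$n_labels,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation recall on noisy simulated fields stays high", {
  found <- 0L; total <- 0L; spurious <- 0L
  for (seed in 1:6) {
    p <- small_field_params(rng_seed = seed)  # default noise_sd = 40
    f <- generate_field(p)
    lm <- segment_nuclei(f$pair$dapi, small_seg_params())
    ct <- assign_max_signal(lm, f$pair$signal)
    total <- total + nrow(f$truth$cells)
    if (nrow(ct)) {
      m <- match_to_truth(ct, f$truth$cells)
      d <- sqrt((f$truth$cells$row[m] - ct$centroid_row)^2 +
                (f$truth$cells$col[m] - ct$centroid_col)^2)
      found <- found + length(unique(m[d < p$nucleus_radius_mean]))
      spurious <- spurious + sum(d >= p$nucleus_radius_mean)
    }
  }
  expect_gte(found / total, 0.95)
  expect_lte(spurious / total, 0.05)
})
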