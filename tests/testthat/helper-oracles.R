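# Independent oracles, deliberately naive: a queue-based flood fill for
# counting connected components and a per-pixel scan for per-label maxima.
# Both are used only to check the package's vectorized implementations.

flood_fill_count <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8L) {
    nbr <- expand.grid(dr = -1:1, dc = -1:1)
    nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  } else {
    nbr <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  count <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] && !seen[r, c]) {
      count <- count + 1L
      queue <- list(c(r, c)); seen[r, c] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbr))) {
          rr <- p[1] + nbr$dr[k]; cc <- p[2] + nbr$dc[k]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  count
}

brute_force_label_max <- function(labels, signal) {
  n <- max(labels)
  out <- rep(-Inf, n)
  for (r in seq_len(nrow(labels))) for (c in seq_len(ncol(labels))) {
    l <- labels[r, c]
    if (l > 0 && signal[r, c] > out[l]) out[l] <- signal[r, c]
  }
  out
}

# Small, fast field parameters shared across tests.
small_field_params <- function(...) {
  args <- utils::modifyList(
    list(image_height = 192, image_width = 192, n_cells = 10,
         nucleus_radius_mean = 7, nucleus_radius_sd = 0.8,
         min_center_separation = 28, positive_fraction = 0.3),
    list(...)
  )
  do.call(sim_field_params, args)
}

small_seg_params <- function(...) {
  segmentation_params(background_radius = 20, min_area = 25,
                      exclude_border = FALSE, ...)
}

# Greedy nearest-centroid matching of segmented cells to ground truth.
match_to_truth <- function(cell_table, truth_cells) {
  vapply(seq_len(nrow(cell_table)), function(i) {
    which.min((truth_cells$row - cell_table$centroid_row[i])^2 +
              (truth_cells$col - cell_table$centroid_col[i])^2)
  }, integer(1))
}
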