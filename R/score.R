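# Per-cell scoring: each segmented cell is assigned the brightest
# background-corrected signal-channel pixel inside its nucleus mask. This
# single number per cell is the statistic that downstream positivity
# classification thresholds.

#' Score each segmented cell by its brightest signal pixel
#'
#' For every label in the segmentation, computes the maximum of the
#' (already background-corrected) signal channel over that label's pixel
#' set, together with the region centroid and area. The signal channel is
#' expected to be background-corrected by the caller (the pipeline applies
#' [subtract_background()] with the same settings as the DAPI channel
#' before scoring).
#'
#' @param label_map A `label_map` from [segment_nuclei()].
#' @param signal Numeric matrix, same shape as the label map.
#' @param metadata Named list (`image_id`, `experiment`, `arm`, `treatment`,
#'   `field`) copied onto every row; missing entries become `NA`.
#' @param max_percentile Percentile of the within-cell intensity
#'   distribution used as the score; the default 100 is the plain maximum
#'   (the study readout). Lower values are available for sensitivity
#'   analysis only.
#' @return A `CellTable` data frame with one row per label, sorted by
#'   label: `image_id`, `experiment`, `arm`, `treatment`, `field`, `label`,
#'   `centroid_row`, `centroid_col`, `area`, `max_signal`.
#' @export
assign_max_signal <- function(label_map, signal, metadata = list(),
                              max_percentile = 100) {
  stopifnot(inherits(label_map, "label_map"), is.matrix(signal))
  if (!all(dim(label_map$labels) == dim(signal))) {
    stop("label map is ", nrow(label_map$labels), "x", ncol(label_map$labels),
         " but signal image is ", nrow(signal), "x", ncol(signal))
  }
  stopifnot(max_percentile > 0, max_percentile <= 100)
  md <- function(key) {
    v <- metadata[[key]]
    if (is.null(v)) NA else v
  }
  n <- label_map$n_labels
  if (n == 0L) {
    return(data.frame(
      image_id = character(0), experiment = character(0),
      arm = character(0), treatment = character(0), field = integer(0),
      label = integer(0), centroid_row = numeric(0),
      centroid_col = numeric(0), area = integer(0), max_signal = numeric(0)
    ))
  }
  lab <- label_map$labels
  idx <- which(lab > 0L)
  labs <- lab[idx]
  vals <- signal[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  fl <- factor(labs, levels = seq_len(n))
  area <- as.integer(tabulate(labs, nbins = n))
  score <- if (max_percentile == 100) {
    as.numeric(tapply(vals, fl, max))
  } else {
    as.numeric(tapply(vals, fl, quantile, probs = max_percentile / 100,
                      names = FALSE))
  }
  data.frame(
    image_id = md("image_id"), experiment = md("experiment"),
    arm = md("arm"), treatment = md("treatment"),
    field = md("field"),
    label = seq_len(n),
    centroid_row = as.numeric(tapply(rows, fl, mean)),
    centroid_col = as.numeric(tapply(cols, fl, mean)),
    area = area,
    max_signal = score,
    stringsAsFactors = FALSE
  )
}
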