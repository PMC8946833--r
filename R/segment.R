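# Nucleus segmentation from the DAPI channel. The DAPI mask defines the
# per-cell regions that are used to crop the gamma-H2AX signal channel:
# background subtraction -> threshold -> connected components -> area /
# border filters -> optional watershed split of touching nuclei.

#' Segmentation parameters
#'
#' @param background_method `"rolling_ball"` (grayscale morphological
#'   opening with a disc, the classic rolling-ball estimate; exact on
#'   constant or ramp backgrounds), `"median"` (median filter) or `"none"`.
#' @param background_radius Radius (pixels) of the background filter. Should
#'   comfortably exceed the nucleus radius so nuclei are not absorbed into
#'   the background estimate.
#' @param dapi_threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold used when
#'   `dapi_threshold_method = "fixed"`.
#' @param min_area,max_area Area bounds (pixels^2) for retained nuclei;
#'   `max_area = NULL` disables the upper bound.
#' @param exclude_border Drop nuclei touching the image border (their
#'   maximum intensity may be truncated by the field of view).
#' @param split_touching Split merged nuclei by watershed on the distance
#'   transform.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#' @return A list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(background_method = c("rolling_ball",
                                                      "median", "none"),
                                background_radius = 50,
                                dapi_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 40, max_area = NULL,
                                exclude_border = TRUE,
                                split_touching = FALSE,
                                connectivity = 8) {
  background_method <- match.arg(background_method)
  dapi_threshold_method <- match.arg(dapi_threshold_method)
  stopifnot(min_area >= 1, connectivity %in% c(4, 8))
  if (background_method != "none") stopifnot(background_radius >= 1)
  if (dapi_threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold must be given when dapi_threshold_method = 'fixed'")
  }
  structure(
    list(background_method = background_method,
         background_radius = background_radius,
         dapi_threshold_method = dapi_threshold_method,
         fixed_threshold = fixed_threshold,
         min_area = min_area, max_area = max_area,
         exclude_border = exclude_border,
         split_touching = split_touching,
         connectivity = as.integer(connectivity)),
    class = "segmentation_params"
  )
}

#' Subtract the background of a fluorescence image
#'
#' Estimates a smooth background and removes it, clipping at zero.
#' `"rolling_ball"` uses grayscale morphological opening with a disc
#' structuring element of the given radius; `"median"` uses a running
#' median of the same radius; `"none"` returns the input unchanged.
#'
#' @param image Numeric matrix `[row, col]`, intensity units.
#' @param method Background method (see [segmentation_params()]).
#' @param radius Filter radius in pixels.
#' @return Background-corrected matrix, same shape, non-negative.
#' @export
subtract_background <- function(image,
                                method = c("rolling_ball", "median", "none"),
                                radius = 50) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "none") return(image)
  stopifnot(radius >= 1)
  if (2 * radius + 1 > min(dim(image))) {
    stop("background radius ", radius, " too large for a ",
         nrow(image), "x", ncol(image), " image")
  }
  mx <- max(image)
  if (mx <= 0) return(image)
  scaled <- image / mx
  bg <- switch(method,
    rolling_ball = EBImage::opening(
      scaled, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")),
    median = EBImage::medianFilter(scaled, as.integer(radius))
  )
  pmax(image - as.matrix(bg) * mx, 0)
}

# Connected-component labeling with selectable connectivity.
# EBImage::bwlabel is 4-connected; 8-connectivity is obtained by merging
# 4-connected labels that touch diagonally (vectorized union-find).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # \ diagonal neighbors
    a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # / diagonal neighbors
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_consecutive(lab)
}

# Re-index positive labels to consecutive 1..n (order of first appearance
# by original label id).
relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    lab[lab > 0L] <- lut[lab[lab > 0L]]
  }
  new_label_map(lab, length(ids))
}

new_label_map <- function(labels, n_labels) {
  structure(list(labels = labels, n_labels = as.integer(n_labels)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", nrow(x$labels), "x", ncol(x$labels), ", ",
      x$n_labels, " labels\n", sep = "")
  invisible(x)
}

#' Segment nuclei from a DAPI image
#'
#' Background-corrects the DAPI channel, thresholds it (Otsu by default),
#' labels connected components, optionally splits touching nuclei by
#' watershed on the distance transform, and applies area and border
#' filters. An all-background image yields an empty label map, not an
#' error.
#'
#' @param dapi Numeric matrix `[row, col]`, single-channel DAPI image.
#' @param params A [segmentation_params()] object.
#' @return A `label_map`: integer matrix `labels` (0 = background, nuclei
#'   labeled consecutively 1..n) and `n_labels`.
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  stopifnot(is.matrix(dapi), inherits(params, "segmentation_params"))
  corrected <- subtract_background(dapi, params$background_method,
                                   params$background_radius)
  mx <- max(corrected)
  if (mx <= 0) {
    return(new_label_map(matrix(0L, nrow(dapi), ncol(dapi)), 0L))
  }
  thr <- switch(params$dapi_threshold_method,
    otsu = EBImage::otsu(EBImage::Image(corrected / mx),
                         range = c(0, 1)) * mx,
    fixed = params$fixed_threshold
  )
  mask <- corrected > thr
  if (!any(mask)) {
    return(new_label_map(matrix(0L, nrow(dapi), ncol(dapi)), 0L))
  }
  if (params$split_touching) {
    dist <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- matrix(as.integer(EBImage::watershed(dist, tolerance = 1)),
                  nrow(dapi))
    lm <- relabel_consecutive(lab)
  } else {
    lm <- label_components(mask, params$connectivity)
  }
  filter_labels(lm, min_area = params$min_area, max_area = params$max_area,
                exclude_border = params$exclude_border)
}

#' Filter a label map by region area and border contact
#'
#' Surviving labels are re-indexed consecutively from 1; the label count
#' never increases.
#'
#' @param label_map A `label_map`.
#' @param min_area Minimum region area in pixels (inclusive).
#' @param max_area Maximum region area, or `NULL` for no upper bound.
#' @param exclude_border Drop regions touching any image edge.
#' @return A filtered `label_map`.
#' @export
filter_labels <- function(label_map, min_area = 1, max_area = NULL,
                          exclude_border = FALSE) {
  stopifnot(inherits(label_map, "label_map"))
  lab <- label_map$labels
  n <- label_map$n_labels
  if (n == 0L) return(label_map)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- areas >= min_area
  if (!is.null(max_area)) keep <- keep & areas <= max_area
  if (exclude_border) {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ],
                           lab[, 1], lab[, ncol(lab)]))
    keep[border_ids[border_ids > 0L]] <- FALSE
  }
  drop_ids <- which(!keep)
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  relabel_consecutive(lab)
}
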