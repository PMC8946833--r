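# Synthetic two-channel fluorescence fields and qPCR Cq tables with exact
# ground truth. The generator reproduces the statistical structure the
# analysis assumes -- fields of non-overlapping round nuclei, a dim/bright
# mixture of gamma-H2AX scores, a smooth background ramp and Gaussian noise --
# so that every downstream stage can be validated against known truth.

# Fraction of a cell's peak signal painted onto the rest of its nucleus disk.
# The single peak pixel (at the rasterized center) carries the full value, so
# the per-cell maximum equals `true_peak_signal` exactly in noise-free fields.
.BODY_FRACTION <- 0.7

#' Parameters for one synthetic fluorescence field
#'
#' Defines the geometry, intensity distributions and noise model of one
#' simulated two-channel (DAPI + signal) field. Intensities are in raw
#' camera units on the `[0, 2^bit_depth - 1]` scale. Cells are round nuclei
#' with Gaussian-perturbed radius; each cell draws its peak signal intensity
#' from either the negative (dim) or positive (bright) distribution.
#'
#' @param image_height,image_width Field size in pixels.
#' @param n_cells Number of nuclei to place (placement fails loudly if they
#'   cannot all be fitted at the required separation).
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius distribution
#'   (pixels).
#' @param min_center_separation Minimum Euclidean distance between nucleus
#'   centers (pixels). A value above twice the largest radius guarantees
#'   non-touching nuclei.
#' @param positive_fraction Probability that a cell is gamma-H2AX positive.
#' @param neg_signal_mean,neg_signal_sd Peak-signal distribution of negative
#'   (dim) cells, in intensity units above background.
#' @param pos_signal_mean,pos_signal_sd Peak-signal distribution of positive
#'   (bright) cells; `pos_signal_mean` must exceed `neg_signal_mean`.
#' @param dapi_mean,dapi_sd Per-cell DAPI intensity distribution above
#'   background.
#' @param background_level Flat background offset added to both channels.
#' @param background_gradient_amplitude Peak-to-peak amplitude of a planar
#'   illumination ramp added to both channels.
#' @param noise_sd Standard deviation of additive Gaussian read noise.
#' @param bit_depth 8 or 16; intensities are clipped to `[0, 2^bit_depth - 1]`.
#' @param rng_seed Optional integer seed; when supplied, [generate_field()]
#'   is fully deterministic.
#'
#' @return A list of class `"sim_field_params"`.
#' @seealso [generate_field()]
#' @export
sim_field_params <- function(image_height = 1024, image_width = 1024,
                             n_cells = 150,
                             nucleus_radius_mean = 12, nucleus_radius_sd = 1.5,
                             min_center_separation = 34,
                             positive_fraction = 0.1,
                             neg_signal_mean = 500, neg_signal_sd = 80,
                             pos_signal_mean = 3000, pos_signal_sd = 300,
                             dapi_mean = 3000, dapi_sd = 300,
                             background_level = 200,
                             background_gradient_amplitude = 100,
                             noise_sd = 40,
                             bit_depth = 16,
                             rng_seed = NULL) {
  p <- list(
    image_height = image_height, image_width = image_width, n_cells = n_cells,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    min_center_separation = min_center_separation,
    positive_fraction = positive_fraction,
    neg_signal_mean = neg_signal_mean, neg_signal_sd = neg_signal_sd,
    pos_signal_mean = pos_signal_mean, pos_signal_sd = pos_signal_sd,
    dapi_mean = dapi_mean, dapi_sd = dapi_sd,
    background_level = background_level,
    background_gradient_amplitude = background_gradient_amplitude,
    noise_sd = noise_sd, bit_depth = bit_depth, rng_seed = rng_seed
  )
  class(p) <- "sim_field_params"
  validate_field_params(p)
  p
}

validate_field_params <- function(p) {
  stopifnot(
    p$image_height >= 8, p$image_width >= 8,
    p$n_cells >= 0,
    p$nucleus_radius_mean > 0, p$nucleus_radius_sd >= 0,
    p$min_center_separation > 0,
    p$positive_fraction >= 0, p$positive_fraction <= 1,
    p$neg_signal_mean > 0, p$pos_signal_mean > p$neg_signal_mean,
    p$neg_signal_sd >= 0, p$pos_signal_sd >= 0,
    p$dapi_mean > 0, p$dapi_sd >= 0,
    p$background_level >= 0, p$background_gradient_amplitude >= 0,
    p$noise_sd >= 0
  )
  if (!p$bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16, got ", p$bit_depth)
  }
  invisible(p)
}

# Planar illumination ramp spanning [0, amplitude] across the field diagonal.
.background_field <- function(h, w, level, amplitude) {
  rr <- if (h > 1) (seq_len(h) - 1) / (h - 1) else rep(0, h)
  cc <- if (w > 1) (seq_len(w) - 1) / (w - 1) else rep(0, w)
  level + amplitude * (outer(rr, cc, function(a, b) (a + b) / 2))
}

# Rejection-sample cell centers with pairwise separation >= min_sep and disks
# fully inside the field. Errors (naming the achievable count) rather than
# silently dropping cells.
.place_centers <- function(n, h, w, radii, min_sep, max_attempts = 200L) {
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    margin <- radii[i] + 1
    if (h - 2 * margin <= 0 || w - 2 * margin <= 0) {
      stop("nucleus radius ", round(radii[i], 1),
           " does not fit in a ", h, "x", w, " field")
    }
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      r <- runif(1, margin, h - margin + 1)
      c <- runif(1, margin, w - margin + 1)
      if (i == 1 ||
          all((rows[seq_len(i - 1)] - r)^2 + (cols[seq_len(i - 1)] - c)^2 >=
              min_sep^2)) {
        rows[i] <- r; cols[i] <- c
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could only place ", i - 1L, " of ", n,
           " nuclei at min_center_separation = ", min_sep,
           "; reduce n_cells or the separation")
    }
  }
  cbind(row = rows, col = cols)
}

#' Generate one synthetic two-channel fluorescence field
#'
#' Renders a DAPI channel (one bright disk per nucleus over a smooth
#' background) and a signal channel in which each cell carries a uniform
#' disk at a fraction of its peak value plus a single brightest pixel at
#' exactly `true_peak_signal` (so the per-cell maximum statistic has exact
#' ground truth). A planar illumination ramp and additive Gaussian noise are
#' applied to both channels, and intensities are clipped to the bit range.
#'
#' @param params A [sim_field_params()] object.
#' @param metadata Optional named list (experiment, arm, treatment, field)
#'   attached to the returned image pair.
#'
#' @return A list with components:
#' \describe{
#'   \item{pair}{`fluor_pair`: list with `dapi` and `signal` matrices
#'     (`[row, col]`, intensity units), `bit_depth` and `metadata`.}
#'   \item{truth}{`ground_truth`: `cells` data frame (`cell`, `row`, `col`,
#'     `radius`, `is_positive`, `true_peak_signal`) and
#'     `true_positive_fraction`.}
#' }
#' @examples
#' f <- generate_field(sim_field_params(
#'   image_height = 128, image_width = 128, n_cells = 6,
#'   nucleus_radius_mean = 8, min_center_separation = 26, rng_seed = 1))
#' nrow(f$truth$cells)
#' @export
generate_field <- function(params, metadata = list()) {
  validate_field_params(params)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  h <- params$image_height; w <- params$image_width
  n <- params$n_cells
  max_int <- 2^params$bit_depth - 1

  bg <- .background_field(h, w, params$background_level,
                          params$background_gradient_amplitude)
  dapi <- bg
  signal <- bg

  if (n > 0) {
    radii <- pmax(1, rnorm(n, params$nucleus_radius_mean,
                           params$nucleus_radius_sd))
    centers <- .place_centers(n, h, w, radii, params$min_center_separation)
    is_pos <- runif(n) < params$positive_fraction
    peak <- ifelse(is_pos,
                   rnorm(n, params$pos_signal_mean, params$pos_signal_sd),
                   rnorm(n, params$neg_signal_mean, params$neg_signal_sd))
    peak <- pmax(peak, 1)
    dapi_val <- pmax(rnorm(n, params$dapi_mean, params$dapi_sd), 1)

    for (i in seq_len(n)) {
      cy <- centers[i, "row"]; cx <- centers[i, "col"]; rad <- radii[i]
      r0 <- max(1L, floor(cy - rad)); r1 <- min(h, ceiling(cy + rad))
      c0 <- max(1L, floor(cx - rad)); c1 <- min(w, ceiling(cx + rad))
      rs <- r0:r1; cs <- c0:c1
      # center-in-pixel rasterization: pixel (r, c) covers center (r, c)
      disk <- outer(rs, cs, function(r, c) (r - cy)^2 + (c - cx)^2 <= rad^2)
      dapi[rs, cs][disk] <- dapi[rs, cs][disk] + dapi_val[i]
      signal[rs, cs][disk] <- signal[rs, cs][disk] +
        .BODY_FRACTION * peak[i]
      pr <- min(max(round(cy), r0), r1); pc <- min(max(round(cx), c0), c1)
      signal[pr, pc] <- bg[pr, pc] + peak[i]
    }
    truth_cells <- data.frame(
      cell = seq_len(n),
      row = centers[, "row"], col = centers[, "col"],
      radius = radii, is_positive = is_pos, true_peak_signal = peak
    )
  } else {
    truth_cells <- data.frame(
      cell = integer(0), row = numeric(0), col = numeric(0),
      radius = numeric(0), is_positive = logical(0),
      true_peak_signal = numeric(0)
    )
  }

  if (params$noise_sd > 0) {
    dapi <- dapi + matrix(rnorm(h * w, 0, params$noise_sd), h, w)
    signal <- signal + matrix(rnorm(h * w, 0, params$noise_sd), h, w)
  }
  dapi <- pmin(pmax(dapi, 0), max_int)
  signal <- pmin(pmax(signal, 0), max_int)

  pair <- structure(
    list(dapi = dapi, signal = signal, bit_depth = params$bit_depth,
         metadata = metadata),
    class = "fluor_pair"
  )
  truth <- structure(
    list(cells = truth_cells,
         true_positive_fraction = if (n > 0) mean(truth_cells$is_positive)
                                  else NA_real_,
         n_cells = n),
    class = "ground_truth"
  )
  stopifnot(nrow(truth$cells) == n)
  list(pair = pair, truth = truth)
}

#' Default arm-by-treatment effect layout of the co-stress design
#'
#' Two pre-stress arms (`control` = normal medium, `osmotic` = NaCl-enriched
#' medium) crossed with three treatments (`untreated`, `UV`, `H2O2`). The
#' default multiplicative effects on the positive fraction follow the
#' pattern reported for keratinocyte co-stress experiments: a strong
#' treatment response in the control arm (2.4-fold after UV, 4.7-fold after
#' hydrogen peroxide) that is blunted by osmotic pre-stress (1.2- and
#' 1.9-fold).
#'
#' @param control_uv,control_h2o2,osmotic_uv,osmotic_h2o2 Multiplicative
#'   factors applied to the baseline positive fraction.
#' @return A data frame with columns `arm`, `treatment`, `factor`.
#' @export
costress_arm_effects <- function(control_uv = 2.4, control_h2o2 = 4.7,
                                 osmotic_uv = 1.2, osmotic_h2o2 = 1.9) {
  data.frame(
    arm = rep(c("control", "osmotic"), each = 3),
    treatment = rep(c("untreated", "UV", "H2O2"), 2),
    factor = c(1, control_uv, control_h2o2, 1, osmotic_uv, osmotic_h2o2),
    stringsAsFactors = FALSE
  )
}

#' Parameters for a simulated co-stress experiment
#'
#' @param baseline_positive_fraction Positive fraction of untreated cells.
#' @param arm_effects Data frame (`arm`, `treatment`, `factor`) of
#'   multiplicative effects on the baseline fraction; untreated conditions
#'   must have factor 1. See [costress_arm_effects()].
#' @param n_fields_per_condition Number of imaged fields per condition.
#' @param field_params [sim_field_params()] template shared by all fields
#'   (its `positive_fraction` and `rng_seed` are overridden per condition).
#' @param experiment_id Identifier recorded in all metadata.
#' @param rng_seed Integer seed for the whole experiment.
#' @return A list of class `"sim_experiment_params"`.
#' @export
sim_experiment_params <- function(baseline_positive_fraction = 0.1,
                                  arm_effects = costress_arm_effects(),
                                  n_fields_per_condition = 4,
                                  field_params = sim_field_params(),
                                  experiment_id = "exp1",
                                  rng_seed = NULL) {
  stopifnot(
    baseline_positive_fraction >= 0, baseline_positive_fraction <= 1,
    all(c("arm", "treatment", "factor") %in% names(arm_effects)),
    n_fields_per_condition >= 1
  )
  untreated <- arm_effects[arm_effects$treatment == "untreated", ]
  if (nrow(untreated) == 0 || any(untreated$factor != 1)) {
    stop("arm_effects must contain an untreated condition with factor 1 ",
         "for every arm")
  }
  structure(
    list(baseline_positive_fraction = baseline_positive_fraction,
         arm_effects = arm_effects,
         n_fields_per_condition = n_fields_per_condition,
         field_params = field_params,
         experiment_id = experiment_id,
         rng_seed = rng_seed),
    class = "sim_experiment_params"
  )
}

#' Generate a full simulated co-stress experiment
#'
#' One set of fields per (arm, treatment) condition. Each condition's
#' configured positive fraction is `clamp(baseline * factor, 0, 1)`; each
#' cell's positive label is an independent Bernoulli draw, so realized
#' per-condition fractions are binomial around the configured value.
#'
#' @param params A [sim_experiment_params()] object.
#' @param outdir Optional directory; when given, per-field TIFFs, a manifest
#'   CSV and a ground-truth CSV are written there (see
#'   [write_experiment()]).
#' @return A list with `fields` (named list of [generate_field()] results),
#'   `manifest` (data frame: `image_id`, `dapi_path`, `signal_path`,
#'   `experiment`, `arm`, `treatment`, `field`, `configured_fraction`) and
#'   `params`.
#' @export
generate_experiment <- function(params, outdir = NULL) {
  stopifnot(inherits(params, "sim_experiment_params"))
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  eff <- params$arm_effects
  fields <- list()
  rows <- list()
  for (k in seq_len(nrow(eff))) {
    frac <- params$baseline_positive_fraction * eff$factor[k]
    if (frac > 1 || frac < 0) {
      warning("configured fraction ", signif(frac, 3), " for (",
              eff$arm[k], ", ", eff$treatment[k], ") clamped to [0, 1]")
      frac <- min(max(frac, 0), 1)
    }
    fp <- params$field_params
    fp$positive_fraction <- frac
    fp$rng_seed <- NULL  # one continuous stream from the experiment seed
    for (f in seq_len(params$n_fields_per_condition)) {
      image_id <- paste(params$experiment_id, eff$arm[k], eff$treatment[k],
                        sprintf("f%02d", f), sep = "_")
      md <- list(experiment = params$experiment_id, arm = eff$arm[k],
                 treatment = eff$treatment[k], field = f,
                 image_id = image_id)
      fields[[image_id]] <- generate_field(fp, metadata = md)
      rows[[image_id]] <- data.frame(
        image_id = image_id, dapi_path = NA_character_,
        signal_path = NA_character_,
        experiment = params$experiment_id, arm = eff$arm[k],
        treatment = eff$treatment[k], field = f,
        configured_fraction = frac, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  out <- list(fields = fields, manifest = manifest, params = params)
  if (!is.null(outdir)) out <- write_experiment(out, outdir)
  out
}

#' Write a simulated experiment to disk
#'
#' Writes each field's DAPI and signal channels as single-channel 16-bit
#' TIFFs, the image manifest as `manifest.csv` (with image paths relative
#' to the manifest's directory) and the ground truth as
#' `ground_truth.csv` (columns `image_id`, `cell`, `row`, `col`, `radius`,
#' `is_positive`, `true_peak_signal`).
#'
#' @param experiment Result of [generate_experiment()].
#' @param outdir Output directory (created if missing).
#' @return The experiment with `manifest` paths filled in, invisibly.
#' @export
write_experiment <- function(experiment, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  man <- experiment$manifest
  truth_rows <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$image_id[i]
    fld <- experiment$fields[[id]]
    dp <- file.path(outdir, paste0(id, "_dapi.tif"))
    sp <- file.path(outdir, paste0(id, "_signal.tif"))
    write_intensity_tiff(fld$pair$dapi, dp, fld$pair$bit_depth)
    write_intensity_tiff(fld$pair$signal, sp, fld$pair$bit_depth)
    man$dapi_path[i] <- dp
    man$signal_path[i] <- sp
    tc <- fld$truth$cells
    if (nrow(tc) > 0) {
      truth_rows[[id]] <- cbind(image_id = id, tc)
    }
  }
  # manifest.csv stores paths relative to its own directory so the
  # experiment folder is relocatable and identical seeds give identical files
  man_disk <- man
  man_disk$dapi_path <- basename(man_disk$dapi_path)
  man_disk$signal_path <- basename(man_disk$signal_path)
  utils::write.csv(man_disk, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(image_id = character(0))
  utils::write.csv(truth, file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE)
  experiment$manifest <- man
  invisible(experiment)
}

#' Parameters for a simulated qPCR Cq table
#'
#' Cq values are constructed by the inverse of the 2^-ddCt model: a treated
#' sample's target-gene Cq is shifted by `-true_log2_fc` cycles relative to
#' control (lower Cq = more transcript), while the reference gene is
#' condition-independent up to noise. Each biological replicate is measured
#' in technical duplicate; duplicate noise is scaled so that the
#' duplicate-averaged Cq has standard deviation `cq_noise_sd`.
#'
#' @param genes Target gene names.
#' @param true_log2_fc Named vector of true log2 fold changes
#'   (treated vs control) per target gene. Defaults follow the qualitative
#'   regulation of the H2AX-phosphorylation network under osmotic stress:
#'   the damage kinases ATM and ATR and the PP4 inhibitor CCDC6 down, the
#'   phosphatase PP4 up.
#' @param reference_gene Reference (housekeeping) gene name; its true
#'   log2 FC is 0 by construction.
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param cq_noise_sd Standard deviation (cycles) of a replicate's
#'   duplicate-averaged Cq.
#' @param reference_cq_mean Mean Cq of the reference gene.
#' @param target_cq_offsets Named vector: control-condition Cq offset of each
#'   target gene above the reference gene.
#' @param rng_seed Integer seed.
#' @return A list of class `"sim_qpcr_params"`.
#' @export
sim_qpcr_params <- function(genes = c("ATM", "ATR", "PP4", "CCDC6"),
                            true_log2_fc = c(ATM = -1, ATR = -0.8,
                                             PP4 = 1, CCDC6 = -1.5),
                            reference_gene = "18S",
                            n_replicates = 3,
                            cq_noise_sd = 0.15,
                            reference_cq_mean = 12,
                            target_cq_offsets = NULL,
                            rng_seed = NULL) {
  stopifnot(n_replicates >= 2, cq_noise_sd >= 0, reference_cq_mean > 0)
  if (!all(genes %in% names(true_log2_fc))) {
    stop("true_log2_fc must name every target gene")
  }
  if (is.null(target_cq_offsets)) {
    target_cq_offsets <- setNames(seq(14, by = 1.5,
                                      length.out = length(genes)), genes)
  }
  structure(
    list(genes = genes, true_log2_fc = true_log2_fc[genes],
         reference_gene = reference_gene, n_replicates = n_replicates,
         cq_noise_sd = cq_noise_sd, reference_cq_mean = reference_cq_mean,
         target_cq_offsets = target_cq_offsets[genes], rng_seed = rng_seed),
    class = "sim_qpcr_params"
  )
}

#' Generate a simulated qPCR Cq table
#'
#' @param params A [sim_qpcr_params()] object.
#' @return A `CqTable` data frame with columns `sample_id`, `condition`
#'   (`control` / `treated`), `gene`, `replicate` (technical duplicate
#'   index), `cq`.
#' @examples
#' tab <- generate_qpcr_table(sim_qpcr_params(cq_noise_sd = 0, rng_seed = 1))
#' head(tab)
#' @export
generate_qpcr_table <- function(params) {
  stopifnot(inherits(params, "sim_qpcr_params"))
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  # technical duplicates carry sqrt(2) * cq_noise_sd each, so their mean has
  # sd cq_noise_sd
  dup_sd <- params$cq_noise_sd * sqrt(2)
  all_genes <- c(params$reference_gene, params$genes)
  rows <- list()
  for (cond in c("control", "treated")) {
    for (rep_i in seq_len(params$n_replicates)) {
      sample_id <- paste0(cond, "_s", rep_i)
      for (g in all_genes) {
        if (g == params$reference_gene) {
          mu <- params$reference_cq_mean
        } else {
          mu <- params$reference_cq_mean + params$target_cq_offsets[[g]]
          if (cond == "treated") mu <- mu - params$true_log2_fc[[g]]
        }
        cq <- mu + if (dup_sd > 0) rnorm(2, 0, dup_sd) else c(0, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, condition = cond, gene = g,
          replicate = 1:2, cq = cq, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-cell scores for a co-stress experiment without rendering
#'
#' Draws each cell's positivity label and peak signal directly from the
#' field parameters' intensity distributions -- i.e. the distribution of
#' per-cell maximum scores under perfect imaging -- skipping pixel
#' rendering and segmentation. Intended for statistical studies (power,
#' calibration) of the classification and fold-change stages, where
#' rendering every field would add nothing but runtime.
#'
#' @param params A [sim_experiment_params()] object.
#' @param n_cells_per_condition Number of cells drawn per (arm, treatment)
#'   condition (overrides the field template's `n_cells` x field count).
#' @return A `CellTable` data frame with the usual columns plus
#'   `is_positive` (ground truth); `field` splits the cells evenly into
#'   `n_fields_per_condition` pseudo-fields.
#' @export
simulate_costress_scores <- function(params, n_cells_per_condition = 500) {
  stopifnot(inherits(params, "sim_experiment_params"),
            n_cells_per_condition >= 1)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  fp <- params$field_params
  eff <- params$arm_effects
  rows <- list()
  for (k in seq_len(nrow(eff))) {
    frac <- min(max(params$baseline_positive_fraction * eff$factor[k], 0), 1)
    n <- n_cells_per_condition
    is_pos <- runif(n) < frac
    score <- ifelse(is_pos,
                    rnorm(n, fp$pos_signal_mean, fp$pos_signal_sd),
                    rnorm(n, fp$neg_signal_mean, fp$neg_signal_sd))
    score <- pmax(score, 0)
    rows[[k]] <- data.frame(
      image_id = paste(params$experiment_id, eff$arm[k], eff$treatment[k],
                       sep = "_"),
      experiment = params$experiment_id,
      arm = eff$arm[k], treatment = eff$treatment[k],
      field = rep_len(seq_len(params$n_fields_per_condition), n),
      label = seq_len(n),
      centroid_row = NA_real_, centroid_col = NA_real_,
      area = NA_integer_,
      max_signal = score,
      is_positive = is_pos,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
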