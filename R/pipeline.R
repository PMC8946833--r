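# End-to-end orchestration: image manifest -> segmentation -> per-cell
# scores -> experiment-anchored positivity -> fold changes and paired
# arm-comparison tests, with provenance written alongside the results.

#' Read and validate an image manifest
#'
#' The manifest is a CSV with one row per imaged field and columns
#' `image_id`, `dapi_path`, `signal_path`, `experiment`, `arm`,
#' `treatment`, `field`. All problems (missing columns, duplicated ids,
#' unreadable files) are collected and reported together.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced image file exists.
#' @return The validated manifest data frame.
#' @export
read_image_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "dapi_path", "signal_path", "experiment", "arm",
           "treatment", "field")
  # relative image paths are resolved against the manifest's directory
  resolve <- function(p) {
    rel <- !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(dirname(path), p[rel])
    p
  }
  if (all(c("dapi_path", "signal_path") %in% names(man))) {
    man$dapi_path <- resolve(man$dapi_path)
    man$signal_path <- resolve(man$signal_path)
  }
  problems <- character(0)
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing_cols, collapse = ", ")))
  } else {
    dup <- man$image_id[duplicated(man$image_id)]
    if (length(dup)) {
      problems <- c(problems, paste0("duplicated image_id: ",
                                     paste(unique(dup), collapse = ", ")))
    }
    if (check_files) {
      paths <- c(man$dapi_path, man$signal_path)
      absent <- unique(paths[!file.exists(paths)])
      if (length(absent)) {
        problems <- c(problems, paste0("missing image file: ", absent))
      }
    }
  }
  if (length(problems)) {
    stop("invalid image manifest ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  man
}

#' Segment and score a list of image pairs
#'
#' Applies [subtract_background()] to both channels (same settings),
#' [segment_nuclei()] to the DAPI channel and [assign_max_signal()] to the
#' signal channel of each field, concatenating the per-cell rows.
#'
#' @param pairs List of `fluor_pair` objects (see [generate_field()]).
#' @param seg_params A [segmentation_params()] object.
#' @return A `CellTable` data frame over all fields.
#' @export
quantify_pairs <- function(pairs, seg_params = segmentation_params()) {
  tables <- lapply(pairs, function(p) {
    lm <- segment_nuclei(p$dapi, seg_params)
    sig <- subtract_background(p$signal, seg_params$background_method,
                               seg_params$background_radius)
    assign_max_signal(lm, sig, metadata = p$metadata)
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' Positivity analysis of a cell table, anchored per experiment
#'
#' For each experiment, derives one positivity threshold from the
#' untreated cells of the control arm (or one per arm when
#' `per_arm = TRUE`) and applies it, unchanged, to every condition of that
#' experiment.
#'
#' @param cells `CellTable` over one or more experiments.
#' @param threshold_method,method_params Passed to [derive_threshold()].
#' @param control_arm Arm whose untreated cells anchor the threshold.
#' @param untreated_label Treatment label of the untreated condition.
#' @param per_arm Derive a separate threshold from each arm's own
#'   untreated cells (sensitivity analysis) instead of one per experiment.
#' @return List: `thresholds` (named list of `experiment_threshold`,
#'   keyed `experiment` or `experiment.arm`), `positivity` (pooled
#'   `PositivitySummary`, one row per experiment x arm x treatment) and
#'   `per_field` (per-field percent positive, for dispersion diagnostics).
#' @export
analyze_positivity <- function(cells,
                               threshold_method = "mean_k_sd",
                               method_params = list(),
                               control_arm = "control",
                               untreated_label = "untreated",
                               per_arm = FALSE) {
  stopifnot(nrow(cells) > 0)
  thresholds <- list()
  pos_rows <- list()
  field_rows <- list()
  for (ex in unique(cells$experiment)) {
    sub <- cells[cells$experiment == ex, , drop = FALSE]
    arms <- unique(sub$arm)
    for (arm in arms) {
      if (per_arm) {
        ctrl <- sub[sub$arm == arm & sub$treatment == untreated_label, ,
                    drop = FALSE]
        key <- paste(ex, arm, sep = ".")
      } else {
        ctrl <- sub[sub$arm == control_arm &
                    sub$treatment == untreated_label, , drop = FALSE]
        key <- ex
      }
      if (nrow(ctrl) == 0) {
        stop("experiment ", ex, ": no untreated '",
             if (per_arm) arm else control_arm,
             "' cells to anchor the threshold")
      }
      if (is.null(thresholds[[key]])) {
        thresholds[[key]] <- derive_threshold(
          ctrl, method = threshold_method, method_params = method_params,
          experiment = ex)
      }
      thr <- thresholds[[key]]
      for (tr in unique(sub$treatment[sub$arm == arm])) {
        cond <- sub[sub$arm == arm & sub$treatment == tr, , drop = FALSE]
        pos_rows[[paste(ex, arm, tr)]] <- count_positive(cond, thr)
        for (f in unique(cond$field)) {
          fc_cells <- cond[cond$field == f, , drop = FALSE]
          s <- count_positive(fc_cells, thr, check_experiment = FALSE)
          s$field <- f
          field_rows[[paste(ex, arm, tr, f)]] <- s
        }
      }
    }
  }
  positivity <- do.call(rbind, pos_rows)
  per_field <- do.call(rbind, field_rows)
  rownames(positivity) <- rownames(per_field) <- NULL
  list(thresholds = thresholds, positivity = positivity,
       per_field = per_field)
}

#' Run the full co-stress image-analysis pipeline
#'
#' Reads the image manifest, segments and scores every field, derives one
#' positivity threshold per experiment from the untreated control,
#' computes percent-positive cells per condition, treated-vs-untreated
#' fold changes per arm, and paired t-tests comparing each osmotic arm
#' against the control arm across replicate experiments. All result
#' tables, the thresholds and a provenance manifest are written to
#' `outdir` when given.
#'
#' @param config Named list (or path to a JSON file with the same fields):
#'   \describe{
#'     \item{manifest}{manifest CSV path (required unless `pairs` given).}
#'     \item{outdir}{output directory; omit to skip writing.}
#'     \item{segmentation}{named list of [segmentation_params()]
#'       arguments.}
#'     \item{threshold_method, threshold_params}{see [derive_threshold()].}
#'     \item{control_arm, untreated_label, per_arm_thresholds}{threshold
#'       anchoring (defaults `"control"`, `"untreated"`, `FALSE`).}
#'     \item{alpha}{significance level (default 0.05).}
#'     \item{grubbs}{apply Grubbs exclusion in the arm comparison
#'       (default `TRUE`).}
#'   }
#' @param pairs Optional list of in-memory `fluor_pair` objects, bypassing
#'   the manifest/file stage (used by simulations and tests).
#' @return List: `cells`, `thresholds`, `positivity`, `per_field`,
#'   `fold_changes`, `arm_tests`, `config`.
#' @export
run_costress_pipeline <- function(config = list(), pairs = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(manifest = NULL, outdir = NULL, segmentation = list(),
         threshold_method = "mean_k_sd", threshold_params = list(),
         control_arm = "control", untreated_label = "untreated",
         per_arm_thresholds = FALSE, alpha = 0.05, grubbs = TRUE),
    config
  )
  if (is.null(pairs)) {
    if (is.null(cfg$manifest)) {
      stop("config$manifest is required when no in-memory pairs are given")
    }
    man <- read_image_manifest(cfg$manifest)
    pairs <- lapply(seq_len(nrow(man)), function(i) {
      structure(
        list(dapi = read_intensity_image(man$dapi_path[i]),
             signal = read_intensity_image(man$signal_path[i]),
             metadata = list(image_id = man$image_id[i],
                             experiment = man$experiment[i],
                             arm = man$arm[i],
                             treatment = man$treatment[i],
                             field = man$field[i])),
        class = "fluor_pair")
    })
  } else {
    man <- NULL
  }
  seg <- do.call(segmentation_params, cfg$segmentation)
  cells <- quantify_pairs(pairs, seg)
  if (nrow(cells) == 0) stop("no cells segmented in any image")
  pos <- analyze_positivity(
    cells, threshold_method = cfg$threshold_method,
    method_params = cfg$threshold_params,
    control_arm = cfg$control_arm,
    untreated_label = cfg$untreated_label,
    per_arm = cfg$per_arm_thresholds
  )
  fc <- compute_fold_changes(pos$positivity,
                             untreated_label = cfg$untreated_label)
  other_arms <- setdiff(unique(fc$arm), cfg$control_arm)
  arm_tests <- NULL
  if (length(other_arms) &&
      length(unique(fc$experiment[!fc$undefined])) >= 2) {
    tests <- lapply(other_arms, function(a) {
      tab <- compare_arms(fc[fc$arm %in% c(cfg$control_arm, a), ],
                          arms = c(cfg$control_arm, a),
                          alpha = cfg$alpha, grubbs = cfg$grubbs)
      if (!is.null(tab) && nrow(tab)) cbind(comparison_arm = a, tab)
    })
    tests <- tests[!vapply(tests, is.null, logical(1))]
    if (length(tests)) arm_tests <- do.call(rbind, tests)
  }
  result <- list(cells = cells, thresholds = pos$thresholds,
                 positivity = pos$positivity, per_field = pos$per_field,
                 fold_changes = fc, arm_tests = arm_tests, config = cfg)
  if (!is.null(cfg$outdir)) {
    write_pipeline_results(result, cfg$outdir, manifest = man)
  }
  result
}

# Write result CSVs, per-experiment threshold JSON and a provenance
# manifest. The CSVs are deterministic given config and inputs; the run
# manifest additionally records hashes, versions and a timestamp.
write_pipeline_results <- function(result, outdir, manifest = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$cells, file.path(outdir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(result$positivity, file.path(outdir, "positivity.csv"),
                   row.names = FALSE)
  utils::write.csv(result$per_field,
                   file.path(outdir, "positivity_per_field.csv"),
                   row.names = FALSE)
  utils::write.csv(result$fold_changes,
                   file.path(outdir, "fold_changes.csv"), row.names = FALSE)
  if (!is.null(result$arm_tests)) {
    utils::write.csv(result$arm_tests, file.path(outdir, "arm_tests.csv"),
                     row.names = FALSE)
  }
  thr <- lapply(result$thresholds, function(t) {
    list(experiment = t$experiment, threshold = t$threshold,
         method = t$method, method_params = t$method_params,
         source_condition = as.list(t$source_condition),
         n_control_cells = t$n_control_cells)
  })
  jsonlite::write_json(thr, file.path(outdir, "thresholds.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  prov <- list(
    package_version = as.character(utils::packageVersion("gammahq")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = result$config[setdiff(names(result$config), "outdir")],
    thresholds = thr
  )
  if (!is.null(manifest)) {
    prov$images <- lapply(seq_len(nrow(manifest)), function(i) {
      list(image_id = manifest$image_id[i],
           dapi_md5 = unname(tools::md5sum(manifest$dapi_path[i])),
           signal_md5 = unname(tools::md5sum(manifest$signal_path[i])),
           experiment = manifest$experiment[i],
           threshold = thr[[
             if (manifest$experiment[i] %in% names(thr))
               manifest$experiment[i] else 1L]]$threshold)
    })
  }
  jsonlite::write_json(prov, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
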