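# Relative quantification of TaqMan qPCR data by the 2^-ddCt method:
# technical duplicates are averaged at the Cq level, each sample's target
# Cq is normalized to the reference gene (delta Ct), Grubbs outliers are
# excluded per gene and condition, and the treated-vs-control difference
# of mean delta Ct gives the fold change 2^-ddCt.

#' Reference-normalized Cq difference (delta Ct)
#'
#' @param cq_target,cq_reference Finite Cq values (cycles); vectors are
#'   subtracted elementwise.
#' @return `cq_target - cq_reference` (cycles).
#' @export
delta_ct <- function(cq_target, cq_reference) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference))) {
    stop("Cq values must be finite")
  }
  cq_target - cq_reference
}

# Average technical replicates: one mean Cq per (sample_id, condition, gene).
average_technical_replicates <- function(cq_table) {
  validate_cq_table(cq_table)
  agg <- aggregate(cq ~ sample_id + condition + gene, data = cq_table,
                   FUN = mean)
  agg[order(agg$condition, agg$sample_id, agg$gene), , drop = FALSE]
}

validate_cq_table <- function(cq_table, reference_gene = NULL) {
  req <- c("sample_id", "condition", "gene", "replicate", "cq")
  missing_cols <- setdiff(req, names(cq_table))
  if (length(missing_cols)) {
    stop("Cq table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(cq_table$cq)) || any(cq_table$cq <= 0)) {
    stop("Cq values must be finite and positive")
  }
  if (!is.null(reference_gene)) {
    samples <- unique(cq_table$sample_id)
    has_ref <- unique(cq_table$sample_id[cq_table$gene == reference_gene])
    absent <- setdiff(samples, has_ref)
    if (length(absent)) {
      stop("reference gene '", reference_gene,
           "' missing for sample(s): ", paste(absent, collapse = ", "))
    }
  }
  invisible(cq_table)
}

#' Per-sample delta Ct values from a Cq table
#'
#' Averages technical replicates per (sample, gene), then subtracts each
#' sample's reference-gene mean Cq from every target gene's mean Cq.
#'
#' @param cq_table Data frame with columns `sample_id`, `condition`,
#'   `gene`, `replicate`, `cq`.
#' @param reference_gene Reference gene name (must be measured in every
#'   sample).
#' @return Data frame: `sample_id`, `condition`, `gene`, `delta_ct`.
#' @export
sample_delta_ct <- function(cq_table, reference_gene = "18S") {
  validate_cq_table(cq_table, reference_gene)
  avg <- average_technical_replicates(cq_table)
  ref <- avg[avg$gene == reference_gene, c("sample_id", "cq")]
  names(ref)[2] <- "cq_ref"
  tgt <- avg[avg$gene != reference_gene, , drop = FALSE]
  m <- merge(tgt, ref, by = "sample_id")
  data.frame(
    sample_id = m$sample_id, condition = m$condition, gene = m$gene,
    delta_ct = delta_ct(m$cq, m$cq_ref),
    stringsAsFactors = FALSE
  )
}

#' 2^-ddCt fold change for one gene
#'
#' Applies iterated Grubbs exclusion (see [grubbs_exclude()]) to the
#' treated and control delta-Ct samples separately, then computes
#' `ddct = mean(delta_ct treated) - mean(delta_ct control)` and the fold
#' change `2^-ddct` (`log2_fc = -ddct`).
#'
#' @param delta_ct_treated,delta_ct_control Non-empty numeric vectors of
#'   per-sample delta Ct values (cycles).
#' @param alpha Grubbs significance level.
#' @param apply_grubbs Apply outlier exclusion (skipped automatically for
#'   n < 3).
#' @param gene Optional gene name carried into the result.
#' @return A `DdctResult` data frame (one row): `gene`,
#'   `delta_ct_control`, `delta_ct_treated` (means after exclusion),
#'   `ddct`, `fold_change`, `log2_fc`, `n_control`, `n_treated`,
#'   `n_excluded`.
#' @export
ddct_fold_change <- function(delta_ct_treated, delta_ct_control,
                             alpha = 0.05, apply_grubbs = TRUE,
                             gene = NA_character_) {
  if (length(delta_ct_treated) == 0 || length(delta_ct_control) == 0) {
    stop("delta Ct vectors must be non-empty")
  }
  keep <- function(v) {
    if (apply_grubbs && length(v) >= 3) {
      gr <- grubbs_exclude(v, alpha = alpha)
      list(values = gr$kept_values,
           n_excluded = length(gr$excluded_indices))
    } else {
      list(values = v, n_excluded = 0L)
    }
  }
  tr <- keep(delta_ct_treated)
  ct <- keep(delta_ct_control)
  if (length(tr$values) == 0 || length(ct$values) == 0) {
    stop("all delta Ct values excluded as outliers")
  }
  ddct <- mean(tr$values) - mean(ct$values)
  data.frame(
    gene = gene,
    delta_ct_control = mean(ct$values),
    delta_ct_treated = mean(tr$values),
    ddct = ddct,
    fold_change = 2^(-ddct),
    log2_fc = -ddct,
    n_control = length(ct$values),
    n_treated = length(tr$values),
    n_excluded = tr$n_excluded + ct$n_excluded,
    stringsAsFactors = FALSE
  )
}

#' Full relative-quantification analysis of a Cq table
#'
#' [sample_delta_ct()] followed by [ddct_fold_change()] for every target
#' gene.
#'
#' @inheritParams sample_delta_ct
#' @param alpha Grubbs significance level.
#' @param apply_grubbs Apply per-gene, per-condition outlier exclusion.
#' @return A `DdctResult` data frame, one row per target gene.
#' @examples
#' tab <- generate_qpcr_table(sim_qpcr_params(cq_noise_sd = 0, rng_seed = 1))
#' analyze_qpcr(tab)
#' @export
analyze_qpcr <- function(cq_table, reference_gene = "18S", alpha = 0.05,
                         apply_grubbs = TRUE) {
  dct <- sample_delta_ct(cq_table, reference_gene)
  out <- lapply(sort(unique(dct$gene)), function(g) {
    sub <- dct[dct$gene == g, , drop = FALSE]
    ddct_fold_change(
      delta_ct_treated = sub$delta_ct[sub$condition == "treated"],
      delta_ct_control = sub$delta_ct[sub$condition == "control"],
      alpha = alpha, apply_grubbs = apply_grubbs, gene = g
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
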