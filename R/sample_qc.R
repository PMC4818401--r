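# Sample-level quality control: array noise-metric thresholds, the
# batch-wise Tukey upper-fence rule on per-sample CNV call counts, and
# qPCR replicate QC. A sample failing any rule is excluded from all
# downstream stages.

#' Array QC-metric filter
#'
#' Fails a sample iff `mapd > mapd_max` or `contrast_qc < contrastqc_min`
#' (strict inequalities, so a sample sitting exactly on a threshold
#' passes). MAPD and contrastQC are noise/quality metrics computed by
#' the upstream intensity-processing workflow and are consumed here as
#' given. Samples without metrics (e.g. non-array platforms) pass this
#' rule with a warning.
#'
#' @param phenotypes A `cnv_phenotypes` frame (columns `mapd`,
#'   `contrast_qc` used where present).
#' @param mapd_max MAPD upper bound (default 0.4).
#' @param contrastqc_min contrastQC lower bound (default 0.4).
#' @return Data frame `sample_id`, `mapd`, `contrast_qc`, `pass`.
#' @export
qc_array_metrics <- function(phenotypes, mapd_max = 0.4, contrastqc_min = 0.4) {
  if (any(phenotypes$mapd < 0, na.rm = TRUE))
    .fail("negative MAPD value")
  no_metrics <- is.na(phenotypes$mapd) & is.na(phenotypes$contrast_qc)
  if (any(no_metrics & phenotypes$platform == "ARRAY"))
    warning(sum(no_metrics & phenotypes$platform == "ARRAY"),
            " ARRAY sample(s) without QC metrics pass the metric rule by default")
  fail <- (!is.na(phenotypes$mapd) & phenotypes$mapd > mapd_max) |
    (!is.na(phenotypes$contrast_qc) & phenotypes$contrast_qc < contrastqc_min)
  data.frame(sample_id = phenotypes$sample_id, mapd = phenotypes$mapd,
             contrast_qc = phenotypes$contrast_qc, pass = !fail,
             stringsAsFactors = FALSE)
}

#' Batch-wise call-count outlier filter
#'
#' Within each batch, computes the Tukey-style upper fence
#' `T = Q75 + iqr_mult * (Q75 - Q25)` over per-sample CNV call counts
#' and flags samples whose count strictly exceeds `T`. Samples with no
#' calls count as 0. Quantiles use linear interpolation between order
#' statistics (`stats::quantile` type 7) by default; the estimator is
#' recorded in the output so thresholds can be frozen and reused.
#' Batches come from the phenotype table's `batch_id`; samples without
#' one fall back to their panel.
#'
#' @param calls A `cnv_calls` frame (post any upstream call filtering).
#' @param phenotypes A `cnv_phenotypes` frame defining the sample set.
#' @param iqr_mult Fence multiplier (default 1.5).
#' @param quantile_type `stats::quantile` type (default 7).
#' @return Data frame `sample_id`, `batch`, `n_calls`, `threshold`,
#'   `pass`, with the quantile type as attribute `quantile_type`.
#' @examples
#' ph <- data.frame(sample_id = paste0("S", 1:5),
#'                  phenotype = "CONTROL", panel_id = "p", platform = "ARRAY",
#'                  mapd = NA, contrast_qc = NA, batch_id = "b1")
#' calls <- data.frame(sample_id = rep(ph$sample_id, c(1, 2, 3, 4, 100)),
#'                     chrom = "chr1", start = 1, end = 1000,
#'                     cnv_type = "DEL", copy_number = 1L, n_probes = 10L,
#'                     mean_probe_spacing = NA)
#' qc_batch_outliers(calls, ph)  # fence 7; only the 100-call sample fails
#' @export
qc_batch_outliers <- function(calls, phenotypes, iqr_mult = 1.5,
                              quantile_type = 7) {
  counts <- table(factor(calls$sample_id, levels = phenotypes$sample_id))
  batch <- ifelse(is.na(phenotypes$batch_id) | phenotypes$batch_id == "",
                  phenotypes$panel_id, phenotypes$batch_id)
  n <- as.integer(counts)
  thr <- numeric(length(n))
  for (b in unique(batch)) {
    i <- batch == b
    if (sum(i) < 4L)
      warning("batch '", b, "' has fewer than 4 samples; fence is unstable")
    q <- stats::quantile(n[i], c(0.25, 0.75), type = quantile_type, names = FALSE)
    thr[i] <- q[2] + iqr_mult * (q[2] - q[1])
  }
  res <- data.frame(sample_id = phenotypes$sample_id, batch = batch,
                    n_calls = n, threshold = thr, pass = n <= thr,
                    stringsAsFactors = FALSE)
  attr(res, "quantile_type") <- quantile_type
  attr(res, "iqr_mult") <- iqr_mult
  res
}

#' qPCR replicate-set filter
#'
#' Discards a replicate set iff its confidence is below `min_confidence`,
#' its z-score is at or above `max_z` (the rule is `>=`), or fewer than
#' `min_replicates` of the four technical replicates were usable. The
#' z-score and confidence are computed upstream (their reference —
#' plate or assay — is the caller's responsibility).
#'
#' @param replicate_sets Data frame with columns `sample_id`,
#'   `assay_id`, `n_replicates`, `confidence` (fraction in `[0,1]`),
#'   `z_score`.
#' @param min_confidence Default 0.95.
#' @param max_z Default 2.65.
#' @param min_replicates Default 3.
#' @return The input with a logical `pass` column appended.
#' @export
qc_qpcr_replicates <- function(replicate_sets, min_confidence = 0.95,
                               max_z = 2.65, min_replicates = 3L) {
  rs <- replicate_sets
  if (any(rs$n_replicates > 4L))
    .fail("replicate count exceeds 4")
  if (any(rs$confidence < 0 | rs$confidence > 1, na.rm = TRUE))
    .fail("confidence must be a fraction in [0, 1]")
  rs$pass <- !(rs$confidence < min_confidence | rs$z_score >= max_z |
                 rs$n_replicates < min_replicates)
  rs
}

#' Run all sample-level QC rules
#'
#' Applies the array-metric rule, the batch-wise call-count outlier rule
#' and (when replicate sets are supplied) the qPCR replicate rule, and
#' combines them: a sample is retained iff it passes every applicable
#' rule.
#'
#' @param calls,phenotypes Cohort tables.
#' @param qpcr_replicates Optional qPCR replicate-set frame
#'   (see [qc_qpcr_replicates()]).
#' @param mapd_max,contrastqc_min,iqr_mult,quantile_type Rule thresholds.
#' @param outlier_rule Set `FALSE` to skip the batch call-count fence.
#'   The fence presumes a non-degenerate background call-count
#'   distribution; on data with an essentially zero background rate
#'   (Q75 = IQR = 0) it would flag every sample with any call.
#' @return A `cnv_qc` object: `samples` (per-sample flags), `thresholds`,
#'   and `summary` counts.
#' @export
run_sample_qc <- function(calls, phenotypes, qpcr_replicates = NULL,
                          mapd_max = 0.4, contrastqc_min = 0.4,
                          iqr_mult = 1.5, quantile_type = 7,
                          outlier_rule = TRUE) {
  metrics <- qc_array_metrics(phenotypes, mapd_max, contrastqc_min)
  outl <- qc_batch_outliers(calls, phenotypes, iqr_mult, quantile_type)
  if (!outlier_rule) outl$pass <- TRUE
  samples <- data.frame(sample_id = phenotypes$sample_id,
                        pass_metrics = metrics$pass,
                        n_calls = outl$n_calls,
                        batch_threshold = outl$threshold,
                        pass_outlier = outl$pass,
                        pass_qpcr = TRUE, stringsAsFactors = FALSE)
  if (!is.null(qpcr_replicates)) {
    q <- qc_qpcr_replicates(qpcr_replicates)
    bad <- unique(q$sample_id[!q$pass])
    samples$pass_qpcr <- !samples$sample_id %in% bad
  }
  samples$pass <- samples$pass_metrics & samples$pass_outlier & samples$pass_qpcr
  structure(list(samples = samples,
                 thresholds = list(mapd_max = mapd_max,
                                   contrastqc_min = contrastqc_min,
                                   iqr_mult = iqr_mult,
                                   quantile_type = quantile_type),
                 summary = c(input = nrow(samples),
                             retained = sum(samples$pass),
                             excluded = sum(!samples$pass))),
            class = "cnv_qc")
}

#' @export
print.cnv_qc <- function(x, ...) {
  s <- x$summary
  cat("Sample QC:", s["input"], "samples,", s["retained"], "retained,",
      s["excluded"], "excluded\n")
  cat("  rules failed - metrics:", sum(!x$samples$pass_metrics),
      " call-count outlier:", sum(!x$samples$pass_outlier),
      " qPCR:", sum(!x$samples$pass_qpcr), "\n")
  invisible(x)
}
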