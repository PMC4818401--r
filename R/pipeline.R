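# End-to-end workflow mirroring the staged study design: sample QC ->
# call filters -> discovery-panel screening -> multi-panel association
# (-> breakpoint interpretation when junction sequences are supplied).
# Every excluded sample, call and region is traceable to a rule, and a
# fixed seed plus identical inputs give identical outputs.

#' Pipeline configuration
#'
#' Collects all stage thresholds in one serializable object. Every
#' value has the package default; a run's effective configuration is
#' written alongside its outputs.
#'
#' @param discovery_panel Panel id used for the screening stage.
#' @param mapd_max,contrastqc_min,iqr_mult Sample-QC thresholds.
#' @param outlier_rule Apply the batch call-count fence (see
#'   [run_sample_qc()]).
#' @param min_probes,max_spacing,spacing_rule Per-call probe filter.
#' @param min_region_probes,min_reciprocal_overlap Region filters.
#' @param min_cases,min_cases_one_control,min_carrier_overlap Screening
#'   clauses.
#' @param bonferroni_m,combine_method,n_permutations Association stage.
#' @param seed Seed for the stochastic combination method.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(discovery_panel = "discovery",
                            mapd_max = 0.4, contrastqc_min = 0.4,
                            iqr_mult = 1.5, outlier_rule = TRUE,
                            min_probes = 5L, max_spacing = 1000,
                            spacing_rule = TRUE,
                            min_region_probes = 10L,
                            min_reciprocal_overlap = 0.5,
                            min_cases = 3L, min_cases_one_control = 5L,
                            min_carrier_overlap = 0,
                            bonferroni_m = 3L,
                            combine_method = "pooled_fisher",
                            n_permutations = 10000L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Any key of [pipeline_config()] may appear; unknown keys are an
#' error, missing keys take the package defaults.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    .fail("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

.log_line <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  c(log, line)
}

#' Run the full screening and association pipeline
#'
#' Stages, in order: sample QC (array metrics + batch-wise call-count
#' outliers); per-call probe-support filtering; candidate-region
#' screening on the designated discovery panel (single-linkage regions,
#' region-level technical filters, carrier-count selection clauses);
#' per-panel and combined association for every selected region across
#' all panels; and, when junction sequences are supplied, breakpoint
#' interpretation. No stage consumes anything a prior stage excluded.
#'
#' @param calls A `cnv_calls` frame (all panels).
#' @param phenotypes A `cnv_phenotypes` frame.
#' @param probe_track,gap_track,common_track Optional tracks.
#' @param junctions Optional named list of
#'   `list(ref, del_start, del_end)` junction descriptions to interpret.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all stage outputs,
#'   the run log and the effective config are written there as
#'   TSV/JSON.
#' @return A `cnv_pipeline_result` with components `qc`, `call_verdicts`,
#'   `regions`, `associations` (one `cnv_assoc` per selected region),
#'   `junctions`, `log`, `config`.
#' @export
run_cnv_pipeline <- function(calls, phenotypes, probe_track = NULL,
                             gap_track = NULL, common_track = NULL,
                             junctions = NULL,
                             config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$discovery_panel %in% phenotypes$panel_id)
    .fail("designated discovery panel '", config$discovery_panel,
          "' not present in the phenotype table")
  set.seed(config$seed)
  log <- character()

  # --- stage: sample QC ------------------------------------------------
  qc <- run_sample_qc(calls, phenotypes,
                      mapd_max = config$mapd_max,
                      contrastqc_min = config$contrastqc_min,
                      iqr_mult = config$iqr_mult,
                      outlier_rule = config$outlier_rule)
  keep_ids <- qc$samples$sample_id[qc$samples$pass]
  log <- .log_line(log, "qc", sprintf("%d of %d samples retained",
                                      length(keep_ids), nrow(phenotypes)))
  phenotypes_kept <- phenotypes[phenotypes$sample_id %in% keep_ids, , drop = FALSE]
  calls_kept <- calls[calls$sample_id %in% keep_ids, , drop = FALSE]
  class(calls_kept) <- class(calls)

  # --- stage: call filters --------------------------------------------
  cf <- apply_call_filters(calls_kept, probe_track,
                           min_probes = config$min_probes,
                           max_spacing = config$max_spacing,
                           spacing_rule = config$spacing_rule)
  log <- .log_line(log, "filter", sprintf("%d of %d calls retained",
                                          nrow(cf$calls), nrow(calls_kept)))

  # --- stage: screening on the discovery panel ------------------------
  disc_ids <- phenotypes_kept$sample_id[phenotypes_kept$panel_id ==
                                          config$discovery_panel]
  disc_calls <- cf$calls[cf$calls$sample_id %in% disc_ids, , drop = FALSE]
  class(disc_calls) <- class(cf$calls)
  regions <- screen_regions(disc_calls, phenotypes_kept,
                            probe_track = probe_track, gap_track = gap_track,
                            common_track = common_track,
                            min_cases = config$min_cases,
                            min_cases_one_control = config$min_cases_one_control,
                            min_overlap = config$min_carrier_overlap,
                            min_region_probes = config$min_region_probes,
                            min_reciprocal_overlap = config$min_reciprocal_overlap)
  log <- .log_line(log, "screen",
                   sprintf("%d region(s), %d selected", nrow(regions),
                           sum(regions$selected)))

  # --- stage: association across all panels ---------------------------
  sel <- regions[regions$selected, , drop = FALSE]
  associations <- lapply(seq_len(nrow(sel)), function(i) {
    tabs <- carrier_tables(sel[i, ], cf$calls, phenotypes_kept,
                           min_overlap = config$min_carrier_overlap)
    region_association(tabs, bonferroni_m = config$bonferroni_m,
                       combine_method = config$combine_method,
                       n_permutations = config$n_permutations,
                       seed = config$seed)
  })
  names(associations) <- sel$region_id
  log <- .log_line(log, "assoc", sprintf("%d region(s) tested", length(associations)))

  # --- stage: breakpoints (optional) ----------------------------------
  junction_reports <- NULL
  if (!is.null(junctions)) {
    junction_reports <- lapply(junctions, function(j)
      junction_report(j$ref, j$del_start, j$del_end))
    log <- .log_line(log, "breakpoint",
                     sprintf("%d junction(s) interpreted", length(junction_reports)))
  }

  res <- structure(list(qc = qc, call_verdicts = cf$verdicts,
                        regions = regions, associations = associations,
                        junctions = junction_reports, log = log,
                        config = config),
                   class = "cnv_pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(res$qc$samples, file.path(out_dir, "qc_report.tsv"))
  .write_tsv(res$call_verdicts, file.path(out_dir, "call_verdicts.tsv"))
  .write_tsv(res$regions, file.path(out_dir, "regions.tsv"))
  if (nrow(res$regions))
    write_bed_track(genomic_track(res$regions$chrom, res$regions$start,
                                  res$regions$end, res$regions$region_id),
                    file.path(out_dir, "regions.bed"))
  assoc <- lapply(res$associations, function(a)
    list(panels = a$panels, pooled = a$pooled[-1],
         pooled_table = as.list(a$pooled$table),
         combined = a$combined, p_bonferroni = a$p_bonferroni))
  jsonlite::write_json(assoc, file.path(out_dir, "associations.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(unclass(res$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(out_dir, "run.log"))
  if (!is.null(res$junctions))
    jsonlite::write_json(lapply(res$junctions, function(j)
      list(size_bp = j$size$bp, size_kb = j$size$kb,
           microhomology = j$microhomology,
           top_motif = if (nrow(j$motifs)) j$motifs$kmer[1] else NA,
           repeat_len = j$repeat_homology$length,
           repeat_identity = j$repeat_homology$identity,
           mechanism = j$mechanism)),
      file.path(out_dir, "junctions.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cat("CNV screening pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Summary table in the per-panel association layout
#'
#' One block per selected region: a row per panel with carrier (`cc`)
#' and non-carrier (`wt`) counts, Fisher p and odds ratio; a pooled row
#' with combined carrier frequencies printed to two decimals; the
#' labelled combination row; and the Bonferroni-corrected row.
#'
#' @param result A `cnv_pipeline_result` (or a single `cnv_assoc`).
#' @return A `cnv_report` data frame.
#' @export
make_report <- function(result) {
  assocs <- if (inherits(result, "cnv_assoc"))
    list(region = result) else result$associations
  blocks <- lapply(names(assocs), function(id) {
    a <- assocs[[id]]
    p <- a$panels
    fmt_or <- function(o) ifelse(is.na(o), "",
                                 ifelse(is.infinite(o), "Inf",
                                        format(round(o, 2), nsmall = 2)))
    rows <- data.frame(region = id, row = p$panel_id,
                       case_wt = p$b, case_cc = p$a,
                       control_wt = p$d, control_cc = p$c,
                       freq_cases = "", freq_controls = "",
                       p = signif(p$p, 2), or = fmt_or(p$or),
                       stringsAsFactors = FALSE)
    pooled <- data.frame(region = id, row = "combined",
                         case_wt = a$pooled$table$b, case_cc = a$pooled$table$a,
                         control_wt = a$pooled$table$d,
                         control_cc = a$pooled$table$c,
                         freq_cases = sprintf("%.2f %%", 100 * a$pooled$case_freq),
                         freq_controls = sprintf("%.2f %%",
                                                 100 * a$pooled$control_freq),
                         p = signif(a$pooled$p, 2), or = fmt_or(a$pooled$or),
                         stringsAsFactors = FALSE)
    comb <- data.frame(region = id, row = paste0("combined_", a$combined$method),
                       case_wt = NA, case_cc = NA, control_wt = NA,
                       control_cc = NA, freq_cases = "", freq_controls = "",
                       p = signif(a$combined$p, 2), or = "",
                       stringsAsFactors = FALSE)
    bonf <- data.frame(region = id, row = "bonferroni_corrected",
                       case_wt = NA, case_cc = NA, control_wt = NA,
                       control_cc = NA, freq_cases = "", freq_controls = "",
                       p = signif(a$p_bonferroni, 2), or = "",
                       stringsAsFactors = FALSE)
    rbind(rows, pooled, comb, bonf)
  })
  res <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(region = character(), row = character(), case_wt = numeric(),
               case_cc = numeric(), control_wt = numeric(),
               control_cc = numeric(), freq_cases = character(),
               freq_controls = character(), p = numeric(), or = character(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("cnv_report", "data.frame")
  res
}
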