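# Candidate-region detection: single-linkage clustering of overlapping
# same-type calls into genomic segments, carrier counting by phenotype,
# and the carrier-count selection clauses ((>=3 cases, 0 controls) or
# (>=5 cases, 1 control); >=2 control carriers never selected).

#' Cluster overlapping same-type calls into candidate regions
#'
#' Calls of the same CNV type on the same chromosome that share at least
#' 1 bp are transitively merged (single linkage); the region span is the
#' union of its member calls. Deletions and duplications never share a
#' region, and adjacent-but-not-overlapping calls are not merged. The
#' result is deterministic and independent of input order.
#'
#' @param calls A `cnv_calls` frame (already filtered).
#' @return A `cnv_regions` data frame: `region_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `n_calls`, with a list column `members` holding
#'   the row indices of each region's member calls in `calls`.
#' @export
build_regions <- function(calls) {
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      cnv_type = character(), n_calls = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) {
    empty$members <- list()
    class(empty) <- c("cnv_regions", "data.frame")
    return(empty)
  }
  groups <- split(seq_len(nrow(calls)),
                  list(chrom = calls$chrom, type = calls$cnv_type), drop = TRUE)
  out <- lapply(groups[order(names(groups))], function(rows) {
    ir <- IRanges::IRanges(calls$start[rows], calls$end[rows])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # merge only true overlaps
    hit <- IRanges::findOverlaps(ir, red)
    members <- split(rows[S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit))
    data.frame(chrom = calls$chrom[rows[1]],
               start = IRanges::start(red), end = IRanges::end(red),
               cnv_type = calls$cnv_type[rows[1]],
               n_calls = lengths(members),
               members = I(unname(members)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$cnv_type), , drop = FALSE]
  res <- cbind(region_id = sprintf("%s_%s_%s_%s", res$chrom,
                                   format(res$start, scientific = FALSE, trim = TRUE),
                                   format(res$end, scientific = FALSE, trim = TRUE),
                                   res$cnv_type),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("cnv_regions", "data.frame")
  res
}

#' Count distinct case and control carriers per region
#'
#' A sample is a carrier of a region if any of its same-type calls
#' overlaps the region span by at least `min_overlap` of the call's
#' length (default 0: any overlap). Each sample counts at most once per
#' region regardless of how many calls it contributes.
#'
#' @param regions Output of [build_regions()].
#' @param calls The same `cnv_calls` frame regions were built from.
#' @param phenotypes A `cnv_phenotypes` frame covering every sample in
#'   `calls`.
#' @param min_overlap Minimum overlapping fraction of the call length.
#' @return `regions` with `case_carriers`, `control_carriers` and a
#'   list column `carrier_ids` appended.
#' @export
count_carriers <- function(regions, calls, phenotypes, min_overlap = 0) {
  missing <- setdiff(calls$sample_id, phenotypes$sample_id)
  if (length(missing))
    .fail("calls from sample(s) absent from the phenotype table: ",
          paste(utils::head(missing, 5), collapse = ", "))
  phe <- stats::setNames(phenotypes$phenotype, phenotypes$sample_id)
  carrier_ids <- vector("list", nrow(regions))
  cc <- integer(nrow(regions))
  ctrl <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rows <- regions$members[[i]]
    if (min_overlap > 0 && length(rows)) {
      ov <- pmax(0, pmin(calls$end[rows], regions$end[i]) -
                   pmax(calls$start[rows], regions$start[i]) + 1)
      rows <- rows[ov / cnv_length(calls$start[rows], calls$end[rows]) >= min_overlap]
    }
    ids <- unique(calls$sample_id[rows])
    carrier_ids[[i]] <- ids
    cc[i] <- sum(phe[ids] == "CASE")
    ctrl[i] <- sum(phe[ids] == "CONTROL")
  }
  regions$case_carriers <- cc
  regions$control_carriers <- ctrl
  regions$carrier_ids <- I(carrier_ids)
  regions
}

#' Apply the carrier-count selection clauses
#'
#' A region is selected iff it has at least `min_cases` case carriers
#' and no control carrier, or at least `min_cases_one_control` case
#' carriers and exactly one control carrier. Regions with two or more
#' control carriers are never selected; the unaddressed two-control
#' case is resolved conservatively as not selected and logged with its
#' own reason code. Adding a control carrier to a selected region can
#' only deselect it.
#'
#' @param regions Output of [count_carriers()].
#' @param min_cases Case carriers required with 0 control carriers
#'   (default 3).
#' @param min_cases_one_control Case carriers required with exactly 1
#'   control carrier (default 5).
#' @return `regions` with logical `selected` and a `reason` code:
#'   `cases_no_control`, `cases_one_control`, `insufficient_cases`,
#'   `two_controls`, `excluded_controls`.
#' @export
select_candidates <- function(regions, min_cases = 3L,
                              min_cases_one_control = 5L) {
  cc <- regions$case_carriers
  ctrl <- regions$control_carriers
  sel0 <- cc >= min_cases & ctrl == 0L
  sel1 <- cc >= min_cases_one_control & ctrl == 1L
  regions$selected <- sel0 | sel1
  regions$reason <- ifelse(sel0, "cases_no_control",
                    ifelse(sel1, "cases_one_control",
                    ifelse(ctrl > 2L, "excluded_controls",
                    ifelse(ctrl == 2L, "two_controls", "insufficient_cases"))))
  regions
}

#' Screen calls into selected candidate regions
#'
#' Convenience wrapper: build regions from the screening panel's calls,
#' apply the region-level technical filters, count carriers and apply
#' the selection clauses.
#'
#' @inheritParams count_carriers
#' @inheritParams select_candidates
#' @param probe_track,gap_track,common_track Optional tracks for the
#'   region-level filters (see [apply_region_filters()]).
#' @param min_region_probes,min_reciprocal_overlap Region-filter
#'   thresholds.
#' @return A `cnv_regions` frame with carrier counts, filter survival
#'   and selection flags; dropped regions keep their verdicts in the
#'   `filter_verdicts` attribute.
#' @export
screen_regions <- function(calls, phenotypes, probe_track = NULL,
                           gap_track = NULL, common_track = NULL,
                           min_cases = 3L, min_cases_one_control = 5L,
                           min_overlap = 0, min_region_probes = 10L,
                           min_reciprocal_overlap = 0.5) {
  regions <- build_regions(calls)
  filt <- apply_region_filters(regions, probe_track, gap_track, common_track,
                               min_region_probes, min_reciprocal_overlap)
  regions <- count_carriers(filt$regions, calls, phenotypes, min_overlap)
  regions <- select_candidates(regions, min_cases, min_cases_one_control)
  attr(regions, "filter_verdicts") <- filt$verdicts
  regions
}
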