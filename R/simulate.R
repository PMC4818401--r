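# Synthetic multi-panel cohort generator. Emits segment-level CNV calls
# (not probe signals): planted rare risk CNVs at phenotype-specific
# carrier frequencies, background passenger calls, short false-positive
# calls, batch outlier samples, a regular probe grid, and a truth table,
# so every downstream stage can be tested against known ground truth.

.default_panels <- function() {
  # mirrors the study design: discovery + qPCR replication + UK array
  # replication + two small panels + pooled in-silico controls
  data.frame(
    panel_id = c("discovery", "german_qpcr", "wtccc2", "norwegian",
                 "lithuanian", "insilico"),
    n_cases = c(902L, 453L, 2394L, 252L, 445L, 0L),
    n_controls = c(1564L, 1377L, 4886L, 272L, 1140L, 4505L),
    platform = c("ARRAY", "QPCR", "ARRAY", "ARRAY", "QPCR", "INSILICO"),
    stringsAsFactors = FALSE)
}

.default_risk_cnvs <- function() {
  # three planted loci with the combined case/control carrier
  # frequencies and event sizes of the study's final candidates
  # (15,761 bp deletion; 118,888 bp and 133,901 bp duplications),
  # placed on short synthetic chromosomes
  data.frame(
    name = c("del_a", "dup_b", "dup_c"),
    chrom = c("chr1", "chr2", "chr3"),
    start = c(2000001, 3000001, 4000001),
    end = c(2000001 + 15760, 3000001 + 118887, 4000001 + 133900),
    cnv_type = c("DEL", "DUP", "DUP"),
    case_freq = c(0.0043, 0.0013, 0.0022),
    control_freq = c(0.0011, 0.0001, 0.0003),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the package targets: six
#' case-control panels (a discovery array panel, qPCR and array
#' replication panels, and a pooled in-silico control set) and three
#' planted rare risk CNVs at combined carrier frequencies of
#' 0.43 %/0.11 %, 0.13 %/0.01 % and 0.22 %/0.03 % (cases/controls).
#' Chromosomes are short synthetic coordinate spaces (10 Mb); nothing
#' downstream depends on real genome size.
#'
#' @param seed Integer seed; a fixed seed makes `simulate_cohort()`
#'   fully reproducible.
#' @param panels Data frame `panel_id`, `n_cases`, `n_controls`,
#'   `platform` (`ARRAY`/`QPCR`/`INSILICO`; in-silico panels must have
#'   0 cases).
#' @param risk_cnvs Data frame `name`, `chrom`, `start`, `end`,
#'   `cnv_type`, `case_freq`, `control_freq`; each sample is a carrier
#'   independently with its phenotype's frequency (rare CNVs show no
#'   familial structure once relatives are removed upstream).
#' @param common_cnvs Optional data frame `chrom`, `start`, `end`,
#'   `cnv_type`, `population_freq` of common polymorphic CNVs planted in
#'   both phenotypes; also returned as a known-common-CNV track.
#' @param passenger_rate Expected background rare calls per sample
#'   (Poisson). Default 2, a realistic post-QC rare-call load for a
#'   SNP 6.0 array.
#' @param boundary_jitter_sd SD (bp) of Gaussian jitter applied
#'   independently to each breakpoint of a planted carrier call; jittered
#'   ends snap to the nearest probe because array resolution quantizes
#'   boundaries. 0 disables jitter entirely (calls equal the planted
#'   interval exactly).
#' @param false_positive_rate Expected spurious short low-probe-support
#'   calls per sample (Poisson).
#' @param outlier_fraction Fraction of samples given inflated call
#'   counts, far above the batch Q75 + 1.5 IQR fence.
#' @param probe_spacing_mean Regular probe grid spacing in bp. Default
#'   700, the typical median inter-marker distance of a dense SNP+CN
#'   genotyping array.
#' @param chrom_lengths Named vector of synthetic chromosome lengths.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          panels = .default_panels(),
                          risk_cnvs = .default_risk_cnvs(),
                          common_cnvs = NULL,
                          passenger_rate = 2,
                          boundary_jitter_sd = 2000,
                          false_positive_rate = 0.2,
                          outlier_fraction = 0.01,
                          probe_spacing_mean = 700,
                          chrom_lengths = c(chr1 = 1e7, chr2 = 1e7,
                                            chr3 = 1e7, chr4 = 1e7)) {
  panels <- as.data.frame(panels, stringsAsFactors = FALSE)
  stopifnot(all(c("panel_id", "n_cases", "n_controls", "platform") %in% names(panels)))
  if (any(panels$n_cases < 0) || any(panels$n_controls < 0))
    .fail("panel sizes must be non-negative")
  if (any(toupper(panels$platform) == "INSILICO" & panels$n_cases > 0))
    .fail("in-silico panels are control-only (n_cases must be 0)")
  if (!is.null(risk_cnvs)) {
    risk_cnvs <- as.data.frame(risk_cnvs, stringsAsFactors = FALSE)
    fr <- c(risk_cnvs$case_freq, risk_cnvs$control_freq)
    if (any(fr < 0 | fr > 1)) .fail("carrier frequencies must be in [0, 1]")
    if (any(!risk_cnvs$cnv_type %in% c("DEL", "DUP")))
      .fail("risk cnv_type must be DEL or DUP")
    if (any(risk_cnvs$end <= risk_cnvs$start)) .fail("risk CNV end must exceed start")
    if (is.null(risk_cnvs$name))
      risk_cnvs$name <- sprintf("risk_%d", seq_len(nrow(risk_cnvs)))
  }
  if (!is.null(common_cnvs)) {
    common_cnvs <- as.data.frame(common_cnvs, stringsAsFactors = FALSE)
    if (any(common_cnvs$population_freq < 0 | common_cnvs$population_freq > 1))
      .fail("population frequencies must be in [0, 1]")
  }
  for (r in c(passenger_rate, false_positive_rate, boundary_jitter_sd,
              outlier_fraction))
    if (r < 0) .fail("rates and jitter must be non-negative")
  if (outlier_fraction > 1) .fail("outlier_fraction must be in [0, 1]")
  structure(list(seed = as.integer(seed), panels = panels,
                 risk_cnvs = risk_cnvs, common_cnvs = common_cnvs,
                 passenger_rate = passenger_rate,
                 boundary_jitter_sd = boundary_jitter_sd,
                 false_positive_rate = false_positive_rate,
                 outlier_fraction = outlier_fraction,
                 probe_spacing_mean = probe_spacing_mean,
                 chrom_lengths = chrom_lengths),
            class = "cohort_config")
}

.probe_grid <- function(config) {
  sp <- config$probe_spacing_mean
  chroms <- names(config$chrom_lengths)
  pos <- lapply(chroms, function(ch) seq(sp, config$chrom_lengths[[ch]], by = sp))
  genomic_track(rep(chroms, lengths(pos)), unlist(pos), unlist(pos), "probe")
}

.snap_to_probe <- function(pos, probes) {
  probes[pmax(1L, pmin(length(probes), round(pos / (probes[2] - probes[1]))))]
}

# vectorized call-table builder: probe support and mean intra-call
# spacing looked up from the (sorted) probe track with findInterval
.call_row <- function(sample_id, chrom, start, end, type, track) {
  n <- length(sample_id)
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); type <- rep_len(type, n)
  np <- integer(n); sp <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- sort(track$start[track$chrom == ch])
    if (!length(p)) next
    lo <- findInterval(start[i] - 1, p) + 1L   # first probe >= start
    hi <- findInterval(end[i], p)              # last probe <= end
    cnt <- pmax(0L, hi - lo + 1L)
    np[i] <- cnt
    ok <- cnt > 1L
    sp[i[ok]] <- (p[hi[ok]] - p[lo[ok]]) / (cnt[ok] - 1)
  }
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cnv_type = type, copy_number = ifelse(type == "DEL", 1L, 3L),
             n_probes = np, mean_probe_spacing = sp, stringsAsFactors = FALSE)
}

#' Simulate a multi-panel case-control CNV cohort
#'
#' Each sample carries each configured risk CNV independently with its
#' phenotype-specific frequency; carrier calls are the planted interval
#' plus optional breakpoint jitter snapped to the probe grid. Background
#' passenger calls, short false-positive calls and batch outlier samples
#' are layered on per the configured rates. Identical config and seed
#' give byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return A `cnv_cohort` list: `calls` (a `cnv_calls` frame),
#'   `phenotypes` (a `cnv_phenotypes` frame), `probe_track`,
#'   `common_track` (may be empty), and `truth` (per risk CNV the exact
#'   carrier sample ids; per sample an outlier flag).
#' @examples
#' cfg <- cohort_config(seed = 7, passenger_rate = 0,
#'                      boundary_jitter_sd = 0, false_positive_rate = 0,
#'                      outlier_fraction = 0)
#' coh <- simulate_cohort(cfg)
#' length(coh$truth$carriers)  # one carrier set per planted risk CNV
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  probe_track <- .probe_grid(config)
  chroms <- names(config$chrom_lengths)

  # --- phenotype table -------------------------------------------------
  ph <- do.call(rbind, lapply(seq_len(nrow(config$panels)), function(i) {
    p <- config$panels[i, ]
    n <- p$n_cases + p$n_controls
    if (n == 0L) return(NULL)
    ids <- sprintf("%s_%05d", p$panel_id, seq_len(n))
    data.frame(sample_id = ids,
               phenotype = rep(c("CASE", "CONTROL"), c(p$n_cases, p$n_controls)),
               panel_id = p$panel_id, platform = toupper(p$platform),
               mapd = NA_real_, contrast_qc = NA_real_,
               batch_id = p$panel_id, stringsAsFactors = FALSE)
  }))
  rownames(ph) <- NULL
  is_array <- ph$platform == "ARRAY"
  ph$mapd[is_array] <- round(pmax(0.05, rnorm(sum(is_array), 0.25, 0.04)), 3)
  ph$contrast_qc[is_array] <- round(runif(sum(is_array), 0.8, 3.0), 3)
  class(ph) <- c("cnv_phenotypes", "data.frame")

  calls <- list()
  truth_carriers <- list()

  # --- planted risk CNVs ----------------------------------------------
  if (!is.null(config$risk_cnvs)) for (i in seq_len(nrow(config$risk_cnvs))) {
    rc <- config$risk_cnvs[i, ]
    freq <- ifelse(ph$phenotype == "CASE", rc$case_freq, rc$control_freq)
    hit <- runif(nrow(ph)) < freq
    carriers <- ph$sample_id[hit]
    truth_carriers[[rc$name]] <- carriers
    if (length(carriers)) {
      s <- rep(rc$start, length(carriers))
      e <- rep(rc$end, length(carriers))
      if (config$boundary_jitter_sd > 0) {
        probes <- probe_track$start[probe_track$chrom == rc$chrom]
        s <- .snap_to_probe(s + rnorm(length(s), 0, config$boundary_jitter_sd), probes)
        e <- .snap_to_probe(e + rnorm(length(e), 0, config$boundary_jitter_sd), probes)
        swap <- e <= s
        if (any(swap)) { e[swap] <- pmax(s[swap], e[swap]) + config$probe_spacing_mean }
      }
      calls[[length(calls) + 1L]] <-
        .call_row(carriers, rc$chrom, s, e, rc$cnv_type, probe_track)
    }
  }

  # --- common polymorphic CNVs ----------------------------------------
  common_track <- genomic_track()
  if (!is.null(config$common_cnvs)) {
    cc <- config$common_cnvs
    common_track <- genomic_track(cc$chrom, cc$start, cc$end, cc$cnv_type)
    for (i in seq_len(nrow(cc))) {
      hit <- runif(nrow(ph)) < cc$population_freq[i]
      if (any(hit))
        calls[[length(calls) + 1L]] <- .call_row(ph$sample_id[hit], cc$chrom[i],
                                                 cc$start[i], cc$end[i],
                                                 cc$cnv_type[i], probe_track)
    }
  }

  # --- passengers, false positives, outliers --------------------------
  outliers <- ph$sample_id[runif(nrow(ph)) < config$outlier_fraction]
  n_extra <- 40L  # far above any plausible Tukey fence at the default rates
  rand_calls <- function(ids, mean_len, min_probes_ok) {
    n <- length(ids)
    ch <- sample(chroms, n, replace = TRUE)
    len <- pmax(3 * config$probe_spacing_mean,
                round(rlnorm(n, log(mean_len), 0.6)))
    st <- floor(runif(n, 1, config$chrom_lengths[ch] - len))
    do.call(rbind, lapply(seq_len(n), function(j)
      .call_row(ids[j], ch[j], st[j], st[j] + len[j] - 1,
                sample(c("DEL", "DUP"), 1), probe_track)))
  }
  if (config$passenger_rate > 0) {
    k <- rpois(nrow(ph), config$passenger_rate)
    k[ph$sample_id %in% outliers] <- k[ph$sample_id %in% outliers] + n_extra
    ids <- rep(ph$sample_id, k)
    if (length(ids)) calls[[length(calls) + 1L]] <- rand_calls(ids, 3e4)
  } else if (length(outliers)) {
    calls[[length(calls) + 1L]] <- rand_calls(rep(outliers, each = n_extra), 3e4)
  }
  if (config$false_positive_rate > 0) {
    k <- rpois(nrow(ph), config$false_positive_rate)
    ids <- rep(ph$sample_id, k)
    if (length(ids)) {
      # short, 2-4 probe events: removed by the probe-support filter
      fp <- rand_calls(ids, 2 * config$probe_spacing_mean)
      calls[[length(calls) + 1L]] <- fp
    }
  }

  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), chrom = character(), start = numeric(),
               end = numeric(), cnv_type = character(), copy_number = integer(),
               n_probes = integer(), mean_probe_spacing = numeric(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$sample_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("cnv_calls", "data.frame")

  structure(list(calls = calls, phenotypes = ph, probe_track = probe_track,
                 common_track = common_track,
                 truth = list(carriers = truth_carriers, outliers = outliers),
                 config = config),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("Synthetic CNV cohort:", nrow(x$phenotypes), "samples in",
      length(unique(x$phenotypes$panel_id)), "panel(s);",
      nrow(x$calls), "calls\n")
  cat("  planted risk CNVs:", length(x$truth$carriers),
      " outlier samples:", length(x$truth$outliers), "\n")
  invisible(x)
}

#' Simulate a deletion breakpoint junction
#'
#' Builds a reference-allele sequence `left flank + deleted segment +
#' right flank` with controllable junction features: a shared motif
#' planted immediately at both breakpoints, a chosen microhomology
#' length, and homologous repeats embedded in both flanks at a requested
#' identity (the NAHR-mediating configuration). The deleted allele is
#' exactly `left flank + right flank`.
#'
#' @param del_len Length of the deleted segment (bp).
#' @param flank_len Flank length on each side (bp); must exceed the
#'   motif, microhomology and repeat lengths.
#' @param motif Sequence planted at both breakpoints (start of the
#'   deleted segment and first base after it), `""` for none.
#' @param microhomology_len Junction microhomology to plant; if shorter
#'   than the motif, the motif itself sets the realized microhomology.
#' @param repeat_len Length of the homologous repeat placed at the ends
#'   of both flanks (0 for none).
#' @param repeat_identity Per-base identity of the right-flank repeat
#'   copy relative to the left-flank copy.
#' @param seed Integer seed.
#' @return A `cnv_junction` list: `ref`, `alt` (character sequences),
#'   `del_start`, `del_end` (1-based inclusive, within `ref`), and
#'   `annotations` describing the planted truth.
#' @export
simulate_junction <- function(del_len = 15761, flank_len = 600,
                              motif = "GATCAC", microhomology_len = 0,
                              repeat_len = 0, repeat_identity = 0.9,
                              seed = 1L) {
  hom_len <- max(nchar(motif), microhomology_len)
  if (flank_len <= hom_len) .fail("flank_len must exceed motif/microhomology length")
  if (flank_len < repeat_len) .fail("flank_len must be >= repeat_len")
  if (del_len <= hom_len) .fail("del_len must exceed the planted homology")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n <- 2L * flank_len + del_len
  seq <- sample(bases, n, replace = TRUE)
  del_start <- flank_len + 1L
  del_end <- flank_len + del_len

  if (repeat_len > 0) {
    rep0 <- sample(bases, repeat_len, replace = TRUE)
    mut <- runif(repeat_len) > repeat_identity
    rep1 <- rep0
    rep1[mut] <- vapply(rep0[mut], function(b) sample(setdiff(bases, b), 1), "")
    # repeats flank the deleted segment: end of left flank, start of right
    seq[(del_start - repeat_len):(del_start - 1L)] <- rep0
    seq[(del_end + 1L):(del_end + repeat_len)] <- rep1
  }

  if (hom_len > 0) {
    hom <- if (nchar(motif)) strsplit(toupper(motif), "")[[1]] else character()
    if (length(hom) < hom_len)
      hom <- c(hom, sample(bases, hom_len - length(hom), replace = TRUE))
    seq[del_start:(del_start + hom_len - 1L)] <- hom
    seq[(del_end + 1L):(del_end + hom_len)] <- hom
  }
  # cap realized microhomology at hom_len by forcing divergence after it
  after_l <- del_start + hom_len
  after_r <- del_end + 1L + hom_len
  if (after_r <= n && seq[after_l] == seq[after_r])
    seq[after_r] <- sample(setdiff(bases, seq[after_l]), 1)

  ref <- paste(seq, collapse = "")
  alt <- paste0(substr(ref, 1L, del_start - 1L), substr(ref, del_end + 1L, n))
  structure(list(ref = ref, alt = alt, del_start = del_start, del_end = del_end,
                 annotations = list(motif = motif, microhomology_len = hom_len,
                                    repeat_len = repeat_len,
                                    repeat_identity = repeat_identity,
                                    flank_len = flank_len, del_len = del_len,
                                    seed = seed)),
            class = "cnv_junction")
}

#' Write a simulated junction as FASTA (reference and deleted alleles)
#' @param junction A `cnv_junction`.
#' @param path Output FASTA path.
#' @export
write_junction_fasta <- function(junction, path) {
  x <- Biostrings::DNAStringSet(c(ref = junction$ref, alt = junction$alt))
  names(x) <- c(sprintf("ref del=%d-%d", junction$del_start, junction$del_end),
                "alt deleted_allele")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
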