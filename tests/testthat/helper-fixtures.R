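# Fixture builders and independent oracles shared across the suite.
# All fixtures are constructed in code; nothing is read from disk.

make_phenotypes <- function(ids, phenotype, panel = "p1", platform = "ARRAY",
                            mapd = NA_real_, contrast_qc = NA_real_,
                            batch = panel) {
  res <- data.frame(sample_id = ids, phenotype = toupper(phenotype),
                    panel_id = rep_len(panel, length(ids)),
                    platform = rep_len(toupper(platform), length(ids)),
                    mapd = rep_len(mapd, length(ids)),
                    contrast_qc = rep_len(contrast_qc, length(ids)),
                    batch_id = rep_len(batch, length(ids)),
                    stringsAsFactors = FALSE)
  class(res) <- c("cnv_phenotypes", "data.frame")
  res
}

make_calls <- function(sample_id, start, end, chrom = "chr1", type = "DEL",
                       copy_number = NA_integer_, n_probes = 10L,
                       spacing = NA_real_) {
  n <- length(sample_id)
  res <- data.frame(sample_id = sample_id, chrom = rep_len(chrom, n),
                    start = rep_len(start, n), end = rep_len(end, n),
                    cnv_type = rep_len(type, n),
                    copy_number = rep_len(copy_number, n),
                    n_probes = rep_len(n_probes, n),
                    mean_probe_spacing = rep_len(spacing, n),
                    stringsAsFactors = FALSE)
  class(res) <- c("cnv_calls", "data.frame")
  res
}

# a cohort config with all noise channels off
noise_free_config <- function(seed, panels, risk_cnvs, ...) {
  cohort_config(seed = seed, panels = panels, risk_cnvs = risk_cnvs,
                passenger_rate = 0, boundary_jitter_sd = 0,
                false_positive_rate = 0, outlier_fraction = 0, ...)
}

# independent Fisher oracle: explicit lchoose enumeration over the
# conditional support, minimum-likelihood two-sided rule
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  p <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  min(1, sum(p[p <= p[a - lo + 1] * (1 + 1e-7)]))
}

# brute-force single-linkage oracle: connected components of the
# pairwise overlap graph (same chrom, same type, >= 1 shared bp)
oracle_components <- function(calls) {
  n <- nrow(calls)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (calls$chrom[i] == calls$chrom[j] &&
        calls$cnv_type[i] == calls$cnv_type[j] &&
        calls$start[i] <= calls$end[j] && calls$end[i] >= calls$start[j]) {
      ri <- find(i); rj <- find(j)
      comp[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

random_table <- function(max_total = 60) {
  n <- sample(4:max_total, 1)
  a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
  c <- sample(0:(n - a - b), 1); d <- n - a - b - c
  c(a = a, b = b, c = c, d = d)
}

# Table 1 per-panel carrier (cc) / non-carrier (wt) counts of the
# replicated deletion, cases then controls per panel
del13_panel_tables <- function() {
  res <- data.frame(
    panel_id = c("discovery", "german_qpcr", "wtccc2", "norwegian",
                 "lithuanian", "insilico"),
    a = c(5, 6, 5, 1, 2, 0), b = c(897, 445, 2391, 251, 442, 0),
    c = c(1, 2, 6, 0, 2, 5), d = c(1563, 1272, 4880, 272, 1131, 4500),
    stringsAsFactors = FALSE)
  class(res) <- c("carrier_tables", "data.frame")
  res
}
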