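one_panel <- function(n_cases, n_controls)
  data.frame(panel_id = "discovery", n_cases = n_cases,
             n_controls = n_controls, platform = "ARRAY")

risk_one <- function(case_freq, control_freq = 0)
  data.frame(name = "r1", chrom = "chr1", start = 2e6 + 1, end = 2e6 + 15761,
             cnv_type = "DEL", case_freq = case_freq,
             control_freq = control_freq)

test_that("config validation rejects impossible rates and frequencies", {
  expect_error(cohort_config(risk_cnvs = risk_one(1.2)), "frequencies")
  expect_error(cohort_config(passenger_rate = -1), "non-negative")
  expect_error(cohort_config(panels = data.frame(
    panel_id = "is", n_cases = 5, n_controls = 10, platform = "INSILICO")),
    "control-only")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- cohort_config(seed = 42, panels = one_panel(50, 80),
                       risk_cnvs = risk_one(0.2, 0.05))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("zero risk frequency gives empty truth carrier sets", {
  cfg <- noise_free_config(1, one_panel(30, 30), risk_one(0, 0))
  coh <- simulate_cohort(cfg)
  expect_length(coh$truth$carriers$r1, 0L)
  expect_equal(nrow(coh$calls), 0L)
})

test_that("with noise off every call equals a planted interval exactly", {
  risk <- rbind(risk_one(0.3, 0.1),
                data.frame(name = "r2", chrom = "chr2", start = 5e6,
                           end = 5e6 + 99999, cnv_type = "DUP",
                           case_freq = 0.2, control_freq = 0.2))
  cfg <- noise_free_config(7, one_panel(40, 40), risk)
  coh <- simulate_cohort(cfg)
  expect_gt(nrow(coh$calls), 0L)
  planted <- paste(risk$chrom, risk$start, risk$end, risk$cnv_type)
  observed <- paste(coh$calls$chrom, coh$calls$start, coh$calls$end,
                    coh$calls$cnv_type)
  expect_true(all(observed %in% planted))
  # and the calls are exactly the truth carriers
  for (nm in names(coh$truth$carriers)) {
    r <- risk[risk$name == nm, ]
    got <- coh$calls$sample_id[coh$calls$chrom == r$chrom &
                                 coh$calls$start == r$start]
    expect_setequal(got, coh$truth$carriers[[nm]])
  }
})

test_that("realized carrier counts stay in the central 99% binomial range", {
  cfg <- noise_free_config(1, one_panel(4445, 13635), risk_one(0.0043, 0.0011))
  coh <- simulate_cohort(cfg)
  carriers <- coh$truth$carriers$r1
  is_case <- grepl("^discovery_", carriers) &
    carriers %in% coh$phenotypes$sample_id[coh$phenotypes$phenotype == "CASE"]
  n_case <- sum(is_case)
  n_ctrl <- length(carriers) - n_case
  expect_gte(n_case, qbinom(0.005, 4445, 0.0043))
  expect_lte(n_case, qbinom(0.995, 4445, 0.0043))
  expect_gte(n_ctrl, qbinom(0.005, 13635, 0.0011))
  expect_lte(n_ctrl, qbinom(0.995, 13635, 0.0011))
  # truth and emitted calls agree
  expect_setequal(coh$calls$sample_id, carriers)
})

test_that("mean observed carrier frequency converges to the configured one", {
  # law-of-large-numbers check at n * freq >= 20 per phenotype
  freqs <- vapply(1:20, function(s) {
    coh <- simulate_cohort(noise_free_config(s, one_panel(2000, 2000),
                                             risk_one(0.05, 0.02)))
    carr <- coh$truth$carriers$r1
    ph <- coh$phenotypes
    c(mean(ph$sample_id[ph$phenotype == "CASE"] %in% carr),
      mean(ph$sample_id[ph$phenotype == "CONTROL"] %in% carr))
  }, numeric(2))
  se_case <- sqrt(0.05 * 0.95 / (20 * 2000))
  se_ctrl <- sqrt(0.02 * 0.98 / (20 * 2000))
  expect_lt(abs(mean(freqs[1, ]) - 0.05), 3 * se_case)
  expect_lt(abs(mean(freqs[2, ]) - 0.02), 3 * se_ctrl)
})

test_that("outlier samples exceed the batch call-count fence", {
  cfg <- cohort_config(seed = 3, panels = one_panel(200, 200),
                       risk_cnvs = NULL, passenger_rate = 2,
                       boundary_jitter_sd = 0, false_positive_rate = 0,
                       outlier_fraction = 0.05)
  coh <- simulate_cohort(cfg)
  expect_gt(length(coh$truth$outliers), 0L)
  qc <- qc_batch_outliers(coh$calls, coh$phenotypes)
  flagged <- qc$sample_id[!qc$pass]
  expect_true(all(coh$truth$outliers %in% flagged))
})

test_that("simulated junctions have the planted structure", {
  j <- simulate_junction(del_len = 1000, flank_len = 300, motif = "GATCAC",
                         seed = 11)
  # deleted allele is exactly left flank + right flank
  expect_equal(j$alt, paste0(substr(j$ref, 1, j$del_start - 1),
                             substr(j$ref, j$del_end + 1, nchar(j$ref))))
  # motif sits immediately at both breakpoints
  expect_equal(substr(j$ref, j$del_start, j$del_start + 5), "GATCAC")
  expect_equal(substr(j$ref, j$del_end + 1, j$del_end + 6), "GATCAC")

  # no planted content: junction sequences differ at the first base
  j0 <- simulate_junction(del_len = 1000, flank_len = 300, motif = "",
                          microhomology_len = 0, seed = 12)
  expect_equal(microhomology_length(j0$ref, j0$del_start, j0$del_end), 0L)

  expect_error(simulate_junction(del_len = 100, flank_len = 5,
                                 motif = "GATCACGATCAC"), "flank_len")
})

test_that("junction FASTA round-trips through Biostrings", {
  j <- simulate_junction(del_len = 500, flank_len = 100, seed = 2)
  f <- withr::local_tempfile(fileext = ".fa")
  write_junction_fasta(j, f)
  seqs <- Biostrings::readDNAStringSet(f)
  expect_equal(as.character(seqs[[1]]), j$ref)
  expect_equal(as.character(seqs[[2]]), j$alt)
})
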