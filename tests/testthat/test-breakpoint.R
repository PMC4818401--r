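test_that("event sizes follow the kb rounding convention", {
  expect_equal(event_size(94781525, 94797285)$kb, 15.8)
  expect_equal(event_size(5786323, 5905210)$kb, 119)
  expect_equal(event_size(140390975, 140524875)$kb, 134)
  expect_equal(event_size(94781525, 94797285)$bp, 15761)
  expect_error(event_size(100, 100), "greater than")
})

test_that("junction motif scan finds planted motifs at both breakpoints", {
  j <- simulate_junction(del_len = 2000, flank_len = 300, motif = "GATCAC",
                         seed = 5)
  fl <- junction_flanks(j$ref, j$del_start, j$del_end)
  hits <- junction_motif_scan(fl$left, fl$right)
  expect_true(any(grepl("GATCAC", hits$kmer, fixed = TRUE)))
  top <- hits[grepl("GATCAC", hits$kmer, fixed = TRUE), ][1, ]
  expect_equal(top$pos_left, 1L)
  expect_equal(top$pos_right, 1L)
})

test_that("identical flanks report the full window as one maximal string", {
  s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  hits <- junction_motif_scan(s, s, k_min = 4, k_max = 30, window = 30)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kmer, s)
})

test_that("disjoint alphabets and Ns never match; bad characters error", {
  polyA <- strrep("A", 60)
  polyC <- strrep("C", 60)
  expect_equal(nrow(junction_motif_scan(polyA, polyC)), 0L)
  withN <- paste0(strrep("N", 30), strrep("A", 30))
  expect_false(any(grepl("N", junction_motif_scan(withN, withN)$kmer)))
  expect_error(junction_motif_scan("ACGTX", polyA, window = 5), "non-nucleotide")
  expect_error(junction_motif_scan(polyA, polyC, window = 100),
               "window exceeds")
})

test_that("motif scan equals brute-force k-mer set intersection", {
  set.seed(6)
  brute <- function(L, R, k_min, k_max) {
    all_k <- function(s, k) unique(substring(s, seq_len(nchar(s) - k + 1),
                                             seq_len(nchar(s) - k + 1) + k - 1))
    res <- character()
    for (k in k_max:k_min)
      res <- c(res, intersect(all_k(L, k), all_k(R, k)))
    # maximal only
    res[!vapply(seq_along(res), function(i)
      any(vapply(res[-i], function(o)
        nchar(o) > nchar(res[i]) && grepl(res[i], o, fixed = TRUE),
        logical(1))), logical(1))]
  }
  for (rep in 1:10) {
    L <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(.4, .3, .2, .1)), collapse = "")
    R <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(.4, .3, .2, .1)), collapse = "")
    got <- junction_motif_scan(L, R, k_min = 3, k_max = 12, window = 60)
    expect_setequal(got$kmer, brute(L, R, 3, 12))
  }
})

test_that("microhomology is the shared junction prefix", {
  j <- simulate_junction(del_len = 500, flank_len = 100, motif = "GATCAC",
                         seed = 7)
  expect_equal(microhomology_length(j$ref, j$del_start, j$del_end), 6L)

  j5 <- simulate_junction(del_len = 500, flank_len = 100, motif = "",
                          microhomology_len = 5, seed = 8)
  expect_equal(microhomology_length(j5$ref, j5$del_start, j5$del_end), 5L)

  # deleting one copy of a perfect tandem repeat: microhomology = unit length
  unit <- "GATTACA"
  ref <- paste0("CCCC", unit, unit, "TTTT")  # unit starts with G != T
  expect_equal(microhomology_length(ref, 5, 4 + nchar(unit)), nchar(unit))

  # invariant under appending unrelated sequence beyond the homology
  expect_equal(microhomology_length(paste0(ref, strrep("C", 50)), 5,
                                    4 + nchar(unit)), nchar(unit))
  expect_error(microhomology_length("ACGT", 2, 9), "out of bounds")
})

test_that("mechanism classification is total and threshold-driven", {
  # NAHR: 300 bp flanking repeats at ~90% identity
  jn <- simulate_junction(del_len = 2000, flank_len = 600, motif = "GATCAC",
                          repeat_len = 300, repeat_identity = 0.9, seed = 9)
  rn <- junction_report(jn$ref, jn$del_start, jn$del_end)
  expect_equal(rn$mechanism, "NAHR")
  expect_gte(rn$repeat_homology$length, 100)
  expect_gte(rn$repeat_homology$identity, 0.85)

  # MMEJ: 5 bp microhomology, no repeats
  jm <- simulate_junction(del_len = 2000, flank_len = 600, motif = "",
                          microhomology_len = 5, seed = 10)
  rm <- junction_report(jm$ref, jm$del_start, jm$del_end)
  expect_equal(rm$mechanism, "MMEJ")

  # NHEJ: blunt junction, no repeats
  j0 <- simulate_junction(del_len = 2000, flank_len = 600, motif = "",
                          microhomology_len = 0, seed = 11)
  expect_equal(junction_report(j0$ref, j0$del_start, j0$del_end)$mechanism,
               "NHEJ")

  # long microhomology without repeats falls through to UNCLASSIFIED
  expect_equal(classify_mechanism(15, NULL)$mechanism, "UNCLASSIFIED")

  # exactly one class for every report
  for (mh in c(0, 1, 2, 5, 10, 11, 30))
    expect_length(classify_mechanism(mh, NULL)$mechanism, 1L)

  # raising the repeat threshold above the planted length demotes NAHR
  strict <- junction_report(jn$ref, jn$del_start, jn$del_end,
                            min_repeat_len = 400L)
  expect_false(strict$mechanism == "NAHR")
})

test_that("junction reports carry sizes and print cleanly", {
  j <- simulate_junction(del_len = 15761, flank_len = 300, seed = 12)
  r <- junction_report(j$ref, j$del_start, j$del_end)
  expect_equal(r$size$kb, 15.8)
  expect_output(print(r), "15.8 kb")
  expect_output(print(r), "mechanism")
})
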