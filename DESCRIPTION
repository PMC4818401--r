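Package: rarecnv
Title: Rare Copy-Number Variant Case-Control Screening and Association
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for rare copy-number variant (CNV) case-control
    screening from per-sample segment calls: sample-level quality control
    (array noise metrics, batch-wise Tukey-fence call-count outliers, qPCR
    replicate QC), per-call and per-region technical filters (probe
    support, probe spacing, assembly-gap span, known common-CNV overlap),
    carrier-count candidate-region detection by single-linkage interval
    clustering, per-panel and pooled two-sided Fisher exact association
    with odds ratios and stratified-permutation combination, and
    breakpoint-junction interpretation (shared motifs, microhomology,
    flanking-repeat homology, NAHR/MMEJ/NHEJ mechanism classification).
    Includes a synthetic multi-panel cohort generator with planted risk
    CNVs and a truth table so every stage is testable without raw array
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
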