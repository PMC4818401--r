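---
title: "Carrier-based screening of rare CNVs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier-based screening of rare CNVs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

## The problem and the model

Rare CNVs — deletions or duplications with carrier frequencies below
about 1 % — cannot be tested with ordinary per-marker association
statistics: almost every variant is private or nearly so, and the
asymptotics behind chi-squared tests fail at a handful of carriers.
`rarecnv` implements the carrier-based alternative used in
multi-panel case-control CNV studies of inflammatory bowel disease
and similar complex traits:

1. In a *discovery panel*, overlapping same-type calls are merged into
   candidate genomic segments, and a segment is carried forward when
   case carriers clearly outnumber control carriers.
2. Each candidate is then re-genotyped or re-called in *independent
   panels* (different populations, different platforms: array or
   TaqMan qPCR, plus public in-silico control sets), and association
   is tested panel-wise and combined on 2×2 *carriership* tables —
   carrier vs non-carrier, case vs control — with exact statistics.

The unit of inference is the carrier, not the genotype dose: a sample
contributes once to a region no matter how many calls it has there.
This is deliberate; rare CNV calls are noisy enough that a
carrier/non-carrier dichotomy is the robust statistic.

## Sample QC

Three rules, each traceable per sample in the QC report:

* **Array metrics.** Fail iff `MAPD > 0.4` or `contrastQC < 0.4`
  (strict inequalities; a sample exactly on a threshold passes).
  These noise metrics come from the upstream intensity workflow and
  are consumed as given; samples without metrics pass with a logged
  warning rather than being silently dropped.
* **Batch call-count fence.** Within each batch (the phenotype file's
  batch column, else the panel), samples with more calls than
  `Q75 + 1.5·(Q75 − Q25)` are excluded. Quantiles use linear
  interpolation between order statistics (`stats::quantile` type 7);
  the estimator and multiplier are recorded in the report so
  thresholds can be frozen and reused, which also makes re-running QC
  on the retained set a no-op. The fence presumes a non-degenerate
  background call-count distribution: on data whose background rate is
  essentially zero (e.g. a noise-free simulation where only risk-CNV
  carriers have any call), Q75 and the IQR are both 0 and the rule
  would flag every carrier. `run_sample_qc(outlier_rule = FALSE)`
  exists for exactly that regime, and the noise-free end-to-end tests
  use it.
* **qPCR replicates.** A replicate set is discarded iff confidence
  < 0.95, z-score ≥ 2.65 (the boundary discards), or fewer than 3 of
  the 4 technical replicates were usable. The z-score's reference
  (plate, assay) is the caller's responsibility; the filter only
  applies the thresholds.

## Technical filters

* **Probe support** (per call): keep iff ≥ 5 supporting probes *and*
  mean intra-call spacing ≤ 1 kb, with spacing computed as
  `(last − first probe)/(n − 1)`. The one-kilobase clause removes
  sparse, low-confidence calls; because dense-array spacing hovers
  near this bound the clause can be disabled
  (`spacing_rule = FALSE`), and unknown spacing (no track, no record
  value) passes the clause rather than failing it. When a probe track
  is supplied it overrides the call record's probe count.
* **Gap span** (per region): drop iff gap bp inside the region
  strictly exceed non-gap bp (gaps merged before counting, so
  overlapping gap records are not double-counted).
* **Common-CNV overlap** (per region): drop iff any known common CNV
  reaches reciprocal overlap
  `min(shared/len(region), shared/len(common)) ≥ 0.5`. The 50 %
  default stands in for what was historically a manual inspection
  step; it is configurable and echoed in every report. A common track
  labelled `DEL`/`DUP` is matched type-aware, otherwise
  type-agnostically.
* **Region probe coverage**: drop iff fewer than 10 probes across the
  full region span (counted across the span, not a shared core — the
  narrower reading would require a core definition the screening
  model does not otherwise need).

The filters are independent predicates, so the retained set does not
depend on application order.

## Region screening

Calls of the same type on the same chromosome sharing at least 1 bp
are merged transitively (single linkage, via `IRanges::reduce`);
adjacent-but-not-overlapping calls stay separate, and DEL/DUP never
merge. Single linkage was chosen over reciprocal-overlap clustering
because the screen's job is to define *segments where carriers
accumulate*, not to match event boundaries; the choice is recorded in
the output metadata, and a `min_overlap` carrier-membership fraction
(default 0 = any overlap) is available where stricter membership is
wanted.

Selection clauses on the carrier counts of the screening panel:

* selected iff (case carriers ≥ 3 and control carriers = 0), or
  (case carriers ≥ 5 and control carriers = 1);
* ≥ 2 control carriers never selects. The two-control case sits
  between the stated clauses; it is resolved conservatively as *not
  selected* and logged with its own reason code (`two_controls`) so
  it can be audited separately from `excluded_controls`.

Anti-monotonicity holds by construction: adding a control carrier can
only deselect a region.

## Association statistics

`fisher_two_sided()` computes the exact conditional p-value under the
minimum-likelihood two-sided convention: conditioning on both
margins, sum the hypergeometric probabilities of all tables whose
probability is at most that of the observed table (with the
conventional `1e-7` relative tie tolerance). The suite verifies
agreement with exhaustive enumeration to 12 significant digits on
every 2×2 table with total ≤ 60, and with `stats::fisher.test` on
random tables.

The odds ratio is the unconditional sample estimate `ad/bc`, which is
what published carriership tables print (`5·1563/(897·1) = 8.71`);
`+Inf` when carriers occur only among cases, undefined when there are
no carriers. Confidence intervals use the Woolf log-OR normal method,
applying the Haldane–Anscombe 0.5 correction to all cells only when
some cell is zero. Conditional maximum-likelihood intervals (as
`fisher.test` reports, and as published tables sometimes print) are
systematically wider at these counts; the package's intervals are
labelled with their method so the two are never conflated.

Panels are combined two ways, both deliberately labelled stand-ins:
element-wise pooling followed by an exact test (`pooled_fisher`,
which ignores stratification), and a within-panel label permutation
(`stratified_permutation`) whose statistic is the total case-carrier
count, with the add-one Monte-Carlo estimate
`(1 + #{permuted ≥ observed})/(1 + B)` — valid by construction and
conservative. Per-panel permutation is drawn from the conditional
hypergeometric law, which is exactly the label-permutation
distribution. Dedicated stratified rare-variant meta-analysis methods
(e.g. "Mega-Analysis of Rare Variants") are *not* re-implemented —
their formulas live outside the material this package is built from —
which is why every combined output names its method. Bonferroni
correction defaults to m = 3, the number of loci a typical follow-up
carries, and is configurable.

## Breakpoint interpretation

Event sizes use the 1-based inclusive convention
(`bp = end − start + 1`) and print as kb rounded to one decimal below
100 kb and to the nearest integer above — the convention that turns
15,761 bp into 15.8 kb and 133,901 bp into 134 kb. Published
breakpoint coordinates do not state whether the end base is included;
both conventions round to the same printed kb values, so the
inclusive choice is documented rather than inferred.

For a deletion junction the two diagnostic sequences both read
rightward from their breakpoint (first deleted base; first base after
the deletion). Their longest common prefix is the junction
microhomology; shared k-mers within a window (default 50 bp, k 4–20)
of both breakpoints are reported maximal-only, ordered by length then
position. Flanking-repeat homology is detected by local alignment of
the upstream and downstream flanks with unit match/mismatch scores
and effectively prohibitive gap penalties — an ungapped local
self-comparison. Classification:

* **NAHR** — flanking repeats ≥ 100 bp at ≥ 85 % identity on both
  sides (thresholds configurable and echoed in the report; they are
  conventions, not claims about any locus);
* else **MMEJ** — microhomology 2–10 bp;
* else **NHEJ** — microhomology ≤ 1 bp;
* else **UNCLASSIFIED** (long microhomology without repeats).

Exactly one class fires per report.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it defines the study
conditions the rest of the package is validated under. Defaults
mirror a six-panel design — discovery 902/1564 (array), qPCR
replication 453/1377, a large array replication panel 2394/4886, two
small panels (252/272 array, 445/1140 qPCR) and a 4505-control
in-silico set — with three planted risk CNVs of 15,761, 118,888 and
133,901 bp at case/control carrier frequencies 0.43 %/0.11 %,
0.13 %/0.01 % and 0.22 %/0.03 %. Chromosomes are short synthetic
coordinate spaces (10 Mb); nothing downstream depends on real genome
size.

Modelling choices:

* Carrier status is independent Bernoulli per sample with the
  phenotype's frequency — rare CNVs carry no familial structure once
  relatedness is removed upstream.
* Breakpoint jitter is Gaussian (default sd 2 kb) applied
  independently per end and snapped to the nearest probe, because
  array resolution quantizes boundaries. With `boundary_jitter_sd =
  0` calls equal the planted interval exactly, which is what makes
  exact end-to-end recovery testable.
* The probe grid is regular with 700 bp spacing, a realistic median
  inter-marker distance for a dense SNP+CN array; passenger calls are
  Poisson (default 2/sample) with log-normal lengths, false-positive
  calls are short (2–4 probes, so the probe-support filter removes
  them), and outlier samples (default 1 %) receive ~40 extra calls,
  far above any plausible batch fence.

What the generator does **not** emulate: probe-level intensity (log-R
/ B-allele) noise, locus-specific call sensitivity, platform
differences in breakpoint accuracy, population stratification within
a panel, and relatedness. Passing recovery tests therefore show the
*pipeline logic* is correct under the stated sampling model — they do
not certify performance on raw-intensity data, where call quality
itself dominates.

## Numerical and degenerate-input conventions

* Fisher p with any zero margin is 1 (single-point support).
* Tie comparison in the two-sided rule uses the `1e-7` relative
  tolerance; enumeration oracles in the tests use the same rule, and
  agreement is required to 12 significant digits.
* Quantile estimator for the QC fence: type 7, configurable, always
  recorded.
* BED input is 0-based half-open and converted on read; all internal
  coordinates and all reports are 1-based inclusive. The conversion
  is its own inverse, and round-trip identity is tested.
* Unknown `copy_number` is permitted (qPCR panels report carrier
  status only); the call type is then authoritative, and a stated
  copy number inconsistent with the type is a parse error.
* Deterministic ordering throughout: regions sort by (chrom, start,
  type), motif hits by (k descending, position), and a fixed seed
  makes cohort generation and pipeline runs byte-identical.

## Problem sizes used in the checks

The test suite and acceptance script size their simulations to be
informative at desk scale: exhaustive Fisher enumeration over all
tables with total ≤ 60 (~6.4 × 10⁵ tables); screening recovery on a
noise-free 1000-case/1500-control panel with three planted CNVs at
1 % case frequency; carrier-frequency recovery over 50–200 seeds of a
4445-case/13,635-control cohort at 0.43 %/0.11 %; and the null size
of the exact test over 1000 replicate 500 vs 500 tables at 2 %
carrier frequency. These sizes are the package's own validation
choices and can be scaled up by editing the corresponding arguments.

## Known limitations

* The screening counts of a real study (how many regions survive
  screening and manual curation) are irreproducible without the raw
  cohort; the package validates the rules, not those counts, and the
  automated filters deliberately stand in for manual raw-data
  inspection.
* The combined p-values of stratified rare-variant meta-analysis
  methods are not computed here; the labelled stand-ins answer a
  related but not identical question.
* Repeat-family annotation (e.g. which repeats are Alu elements) is
  out of scope: the NAHR call rests on sequence homology alone, or on
  a user-supplied repeat track.
* The spacing clause of the probe-support filter encodes one reading
  of an ambiguous published rule (drop calls with *sparse* probe
  coverage); the interpretation and its off-switch are both part of
  the public interface.
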