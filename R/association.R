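# Carrier-based association statistics on 2x2 tables: two-sided Fisher
# exact p-values, odds ratios with Woolf confidence intervals, pooling
# across panels, Bonferroni correction, and labelled stand-ins for
# combining stratified panels.

#' Two-sided Fisher exact test on a 2x2 carrier table
#'
#' Exact hypergeometric p-value under the minimum-likelihood two-sided
#' convention: conditioning on both margins, the p-value is the sum of
#' the probabilities of all tables whose probability does not exceed
#' that of the observed table (with the conventional 1e-7 relative
#' tolerance for floating-point ties). This is the convention mainstream
#' exact-test implementations use. Any zero margin gives p = 1.
#'
#' @param a,b Case carriers and case non-carriers.
#' @param c,d Control carriers and control non-carriers.
#' @return The two-sided p-value.
#' @examples
#' fisher_two_sided(5, 897, 1, 1563)   # 0.027
#' fisher_two_sided(6, 445, 2, 1272)   # 0.005
#' @export
fisher_two_sided <- function(a, b, c, d) {
  a <- .assert_scalar_count(a, "a"); b <- .assert_scalar_count(b, "b")
  c <- .assert_scalar_count(c, "c"); d <- .assert_scalar_count(d, "d")
  m <- a + b          # cases
  n <- c + d          # controls
  k <- a + c          # carriers
  lo <- max(0L, k - n)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  min(1, sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval
#'
#' Point estimate is the unconditional sample odds ratio
#' `(a d) / (b c)`; with carriers only among cases (`c = 0`, `a > 0`)
#' the odds ratio is `+Inf`, and with no carriers at all it is
#' undefined (`NA`). The confidence interval uses the log-odds-ratio
#' normal (Woolf) method, with the Haldane–Anscombe 0.5 continuity
#' correction applied to all cells only when some cell is zero.
#'
#' @inheritParams fisher_two_sided
#' @param conf_level Confidence level (default 0.95).
#' @return List `or`, `ci_low`, `ci_high`, `method`, `corrected`.
#' @examples
#' odds_ratio(5, 897, 1, 1563)$or  # 8.71
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  if (a == 0 && c == 0)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                method = "woolf", corrected = FALSE))
  or <- if (c == 0 && a > 0) Inf else (a * d) / (b * c)
  corrected <- any(c(a, b, c, d) == 0)
  cc <- if (corrected) 0.5 else 0
  aa <- a + cc; bb <- b + cc; cc2 <- c + cc; dd <- d + cc
  se <- sqrt(1 / aa + 1 / bb + 1 / cc2 + 1 / dd)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- log((aa * dd) / (bb * cc2))
  list(or = or, ci_low = exp(centre - z * se), ci_high = exp(centre + z * se),
       method = "woolf", corrected = corrected)
}

#' Pool per-panel carrier tables element-wise
#'
#' @param tables A `carrier_tables` data frame with columns `panel_id`,
#'   `a`, `b`, `c`, `d` (one row per panel, disjoint samples).
#' @return A one-row carrier table (`panel_id = "pooled"`) of column
#'   sums; pooled carrier frequencies are `a/(a+b)` and `c/(c+d)`.
#' @export
pool_tables <- function(tables) {
  res <- data.frame(panel_id = "pooled",
                    a = sum(tables$a), b = sum(tables$b),
                    c = sum(tables$c), d = sum(tables$d),
                    stringsAsFactors = FALSE)
  class(res) <- class(tables)
  res
}

#' Bonferroni correction
#'
#' @param p Nominal p-value(s).
#' @param m Number of tests (default 3, the number of loci carried into
#'   follow-up).
#' @return `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = 3L) {
  if (m < 1) .fail("m must be >= 1")
  pmin(1, p * m)
}

#' Combine stratified carrier tables (labelled stand-ins)
#'
#' Neither stand-in is the M.A.R.V. method (whose formula is defined in
#' external work and not re-implemented here); outputs carry their
#' method label so they cannot be mistaken for it.
#' `pooled_fisher` applies the two-sided Fisher exact test to the
#' element-wise pooled table. `stratified_permutation` permutes
#' case/control labels within each panel (equivalently, draws the
#' per-panel case-carrier count from its conditional hypergeometric
#' law), uses the total case-carrier count as statistic, and returns
#' the add-one upper-tail Monte-Carlo p-value
#' `(1 + #[permuted >= observed]) / (1 + B)`.
#'
#' @param tables A `carrier_tables` frame (one row per panel).
#' @param method `"pooled_fisher"` or `"stratified_permutation"`.
#' @param n_permutations Number of label permutations (minimum 100).
#' @param seed Optional seed for the permutation draw.
#' @return List `p`, `method`, and for the permutation method
#'   `n_permutations` and the observed statistic.
#' @export
combine_stratified <- function(tables,
                               method = c("pooled_fisher",
                                          "stratified_permutation"),
                               n_permutations = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (method == "pooled_fisher") {
    pt <- pool_tables(tables)
    return(list(p = fisher_two_sided(pt$a, pt$b, pt$c, pt$d),
                method = "pooled_fisher"))
  }
  if (n_permutations < 100L)
    .fail("n_permutations must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- sum(tables$a)
  stat <- numeric(n_permutations)
  for (i in seq_len(nrow(tables))) {
    t <- tables[i, ]
    stat <- stat + stats::rhyper(n_permutations, t$a + t$c, t$b + t$d, t$a + t$b)
  }
  list(p = (1 + sum(stat >= obs)) / (1 + n_permutations),
       method = "stratified_permutation",
       n_permutations = n_permutations, observed = obs)
}

#' Build per-panel carrier tables for a region
#'
#' A sample is a region carrier if it contributes a same-type call
#' overlapping the region span (any overlap by default, matching
#' [count_carriers()]).
#'
#' @param region One row of a `cnv_regions` frame (or any list with
#'   `chrom`, `start`, `end`, `cnv_type`).
#' @param calls Cohort-wide `cnv_calls` (all panels).
#' @param phenotypes Cohort-wide `cnv_phenotypes`.
#' @param min_overlap Minimum overlapping fraction of the call length.
#' @return A `carrier_tables` data frame, one row per panel in panel
#'   order of first appearance.
#' @export
carrier_tables <- function(region, calls, phenotypes, min_overlap = 0) {
  sel <- calls$cnv_type == region$cnv_type & calls$chrom == region$chrom &
    calls$start <= region$end & calls$end >= region$start
  if (min_overlap > 0) {
    ov <- pmax(0, pmin(calls$end, region$end) - pmax(calls$start, region$start) + 1)
    sel <- sel & ov / cnv_length(calls$start, calls$end) >= min_overlap
  }
  carriers <- unique(calls$sample_id[sel])
  panels <- unique(phenotypes$panel_id)
  out <- lapply(panels, function(p) {
    ph <- phenotypes[phenotypes$panel_id == p, ]
    is_car <- ph$sample_id %in% carriers
    data.frame(panel_id = p,
               a = sum(is_car & ph$phenotype == "CASE"),
               b = sum(!is_car & ph$phenotype == "CASE"),
               c = sum(is_car & ph$phenotype == "CONTROL"),
               d = sum(!is_car & ph$phenotype == "CONTROL"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("carrier_tables", "data.frame")
  res
}

#' Per-panel and combined association statistics for a region
#'
#' Computes, for each panel, the two-sided Fisher exact p-value and the
#' odds ratio with its Woolf confidence interval; pools the panels into
#' a combined table with combined carrier frequencies; applies the
#' configured stratified combination stand-in; and Bonferroni-corrects
#' the pooled p-value.
#'
#' @param tables A `carrier_tables` frame (e.g. from
#'   [carrier_tables()]), one row per panel.
#' @param bonferroni_m Number of tests for the correction (default 3).
#' @param combine_method Passed to [combine_stratified()].
#' @param n_permutations,seed Permutation parameters.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return A `cnv_assoc` object: `panels` (per-panel statistics),
#'   `pooled` (pooled table, frequencies, p, OR), `combined`
#'   (labelled combination stand-in) and `p_bonferroni`.
#' @export
region_association <- function(tables, bonferroni_m = 3L,
                               combine_method = "pooled_fisher",
                               n_permutations = 10000L, seed = NULL,
                               conf_level = 0.95) {
  per_panel <- do.call(rbind, lapply(seq_len(nrow(tables)), function(i) {
    t <- tables[i, ]
    or <- odds_ratio(t$a, t$b, t$c, t$d, conf_level)
    data.frame(panel_id = t$panel_id, a = t$a, b = t$b, c = t$c, d = t$d,
               case_freq = if (t$a + t$b > 0) t$a / (t$a + t$b) else NA_real_,
               control_freq = if (t$c + t$d > 0) t$c / (t$c + t$d) else NA_real_,
               p = fisher_two_sided(t$a, t$b, t$c, t$d),
               or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               stringsAsFactors = FALSE)
  }))
  pt <- pool_tables(tables)
  or_p <- odds_ratio(pt$a, pt$b, pt$c, pt$d, conf_level)
  pooled <- list(table = pt,
                 case_freq = if (pt$a + pt$b > 0) pt$a / (pt$a + pt$b) else NA_real_,
                 control_freq = if (pt$c + pt$d > 0) pt$c / (pt$c + pt$d) else NA_real_,
                 p = fisher_two_sided(pt$a, pt$b, pt$c, pt$d),
                 or = or_p$or, ci_low = or_p$ci_low, ci_high = or_p$ci_high)
  combined <- combine_stratified(tables, combine_method, n_permutations, seed)
  structure(list(panels = per_panel, pooled = pooled, combined = combined,
                 bonferroni_m = bonferroni_m,
                 p_bonferroni = bonferroni(pooled$p, bonferroni_m)),
            class = "cnv_assoc")
}

#' @export
print.cnv_assoc <- function(x, digits = 3, ...) {
  cat("Carrier-based association (two-sided Fisher exact)\n")
  p <- x$panels
  fmt_or <- function(o) ifelse(is.na(o), "NA",
                               ifelse(is.infinite(o), "Inf", format(round(o, 2))))
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-14s %d/%d cases, %d/%d controls  p=%.3g OR=%s\n",
                p$panel_id[i], p$a[i], p$a[i] + p$b[i], p$c[i],
                p$c[i] + p$d[i], p$p[i], fmt_or(p$or[i])))
  cat(sprintf("  pooled: %.2f %% cases vs %.2f %% controls, p=%.3g OR=%s\n",
              100 * x$pooled$case_freq, 100 * x$pooled$control_freq,
              x$pooled$p, fmt_or(x$pooled$or)))
  cat(sprintf("  combined (%s): p=%.3g;  Bonferroni (m=%d): p=%.3g\n",
              x$combined$method, x$combined$p, x$bonferroni_m, x$p_bonferroni))
  invisible(x)
}
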