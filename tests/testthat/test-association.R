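test_that("two-sided Fisher reproduces the printed worked examples", {
  expect_equal(round(fisher_two_sided(5, 897, 1, 1563), 3), 0.027)
  expect_equal(round(fisher_two_sided(6, 445, 2, 1272), 3), 0.005)
  expect_equal(round(fisher_two_sided(4, 898, 0, 1564), 3), 0.018)
  # 2x2 with margins (2,2)/(2,2): all tables qualify, p = 1
  expect_equal(fisher_two_sided(1, 1, 1, 1), 1)
  # any zero margin gives p = 1
  expect_equal(fisher_two_sided(0, 0, 3, 5), 1)
  expect_equal(fisher_two_sided(0, 4, 0, 6), 1)
})

test_that("Fisher p agrees with enumeration and with stats::fisher.test", {
  set.seed(13)
  for (i in 1:300) {
    t <- random_table()
    p <- fisher_two_sided(t["a"], t["b"], t["c"], t["d"])
    expect_lt(abs(p - oracle_fisher_p(t["a"], t["b"], t["c"], t["d"])),
              1e-12 * max(p, 1e-12))
    ft <- fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_lt(abs(p - min(ft, 1)), 1e-10)
  }
})

test_that("Fisher p respects table symmetries and carrier monotonicity", {
  set.seed(14)
  for (i in 1:50) {
    t <- random_table()
    p <- fisher_two_sided(t["a"], t["b"], t["c"], t["d"])
    # swapping both rows and columns leaves p unchanged
    expect_equal(fisher_two_sided(t["d"], t["c"], t["b"], t["a"]), p)
    expect_equal(fisher_two_sided(t["c"], t["d"], t["a"], t["b"]), p)
  }
  # moving case carriers up while holding margins shrinks the upper tail
  tail_p <- function(a, b, c, d)
    phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  for (a in 1:8) expect_lte(tail_p(a + 1, 9 - a, 9 - a, a + 31),
                            tail_p(a, 10 - a, 10 - a, a + 30))
})

test_that("odds ratio matches the printed discovery value and edge cases", {
  expect_equal(round(odds_ratio(5, 897, 1, 1563)$or, 2), 8.71)
  expect_equal(odds_ratio(4, 898, 0, 1564)$or, Inf)
  expect_equal(odds_ratio(1, 1, 1, 1)$or, 1)
  expect_true(is.na(odds_ratio(0, 10, 0, 20)$or))
  # single column swap maps OR to its reciprocal
  o <- odds_ratio(3, 7, 2, 12)
  expect_equal(odds_ratio(2, 12, 3, 7)$or, 1 / o$or)
  # Woolf interval brackets the estimate; Haldane only at zero cells
  expect_false(o$corrected)
  expect_true(o$ci_low < o$or && o$or < o$ci_high)
  expect_true(odds_ratio(4, 898, 0, 1564)$corrected)
})

test_that("pooling sums panels element-wise", {
  tabs <- del13_panel_tables()
  pooled <- pool_tables(tabs)
  expect_equal(pooled$a, 19)
  expect_equal(pooled$b, 4426)
  expect_equal(pooled$c, 16)
  # pooling one table, or adding an all-zero table, is the identity
  one <- tabs[1, ]
  expect_equal(pool_tables(one)[, c("a", "b", "c", "d")],
               one[, c("a", "b", "c", "d")], ignore_attr = TRUE)
  zero <- one; zero[, c("a", "b", "c", "d")] <- 0
  expect_equal(pool_tables(rbind(one, zero))[, c("a", "b", "c", "d")],
               one[, c("a", "b", "c", "d")], ignore_attr = TRUE)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(1.2e-3, 3), 3.6e-3)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(0.1, 0), "m must be")
})

test_that("combination stand-ins are labelled and degenerate cases give p = 1", {
  tabs <- del13_panel_tables()
  tabs[, c("a", "c")] <- 0
  pf <- combine_stratified(tabs, "pooled_fisher")
  sp <- combine_stratified(tabs, "stratified_permutation", 200, seed = 1)
  expect_equal(pf$p, 1)
  expect_equal(sp$p, 1)
  expect_equal(pf$method, "pooled_fisher")
  expect_equal(sp$method, "stratified_permutation")
  expect_error(combine_stratified(tabs, "stratified_permutation", 50),
               "at least 100")
})

test_that("single-panel permutation p matches the exact hypergeometric tail", {
  tab <- data.frame(panel_id = "p1", a = 7, b = 193, c = 2, d = 398)
  class(tab) <- c("carrier_tables", "data.frame")
  exact <- phyper(6, 9, 580, 200, lower.tail = FALSE)  # P(X >= 7)
  res <- combine_stratified(tab, "stratified_permutation",
                            n_permutations = 20000, seed = 2)
  mc_se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$p - exact), 4 * mc_se + 1e-4)
})

test_that("a planted multi-panel enrichment is detected by permutation", {
  set.seed(3)
  tabs <- do.call(rbind, lapply(1:3, function(i) {
    n_case <- 500; n_ctrl <- 800
    a <- rbinom(1, n_case, 0.05); c <- rbinom(1, n_ctrl, 0.005)
    data.frame(panel_id = paste0("p", i), a = a, b = n_case - a,
               c = c, d = n_ctrl - c)
  }))
  class(tabs) <- c("carrier_tables", "data.frame")
  res <- combine_stratified(tabs, "stratified_permutation",
                            n_permutations = 10000, seed = 1)
  expect_lt(res$p, 0.01)
})

test_that("null permutation p-values are stochastically >= uniform", {
  set.seed(4)
  ps <- replicate(150, {
    tabs <- do.call(rbind, lapply(1:3, function(i) {
      a <- rbinom(1, 300, 0.02); c <- rbinom(1, 500, 0.02)
      data.frame(panel_id = paste0("p", i), a = a, b = 300 - a,
                 c = c, d = 500 - c)
    }))
    class(tabs) <- c("carrier_tables", "data.frame")
    combine_stratified(tabs, "stratified_permutation", 400)$p
  })
  for (t in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 150))
})

test_that("region_association assembles panel, pooled and corrected rows", {
  a <- region_association(del13_panel_tables(), bonferroni_m = 3)
  expect_s3_class(a, "cnv_assoc")
  expect_equal(nrow(a$panels), 6)
  expect_equal(round(a$panels$p[1], 3), 0.027)
  expect_equal(round(a$panels$or[1], 2), 8.71)
  expect_equal(round(100 * a$pooled$case_freq, 2), 0.43)
  expect_equal(a$p_bonferroni, min(1, 3 * a$pooled$p))
  expect_output(print(a), "0.43 % cases")
})

test_that("carrier tables count region carriers per panel", {
  ph <- rbind(make_phenotypes(paste0("A", 1:6), rep(c("case", "control"), 3),
                              panel = "p1"),
              make_phenotypes(paste0("B", 1:4), rep(c("case", "control"), 2),
                              panel = "p2"))
  class(ph) <- c("cnv_phenotypes", "data.frame")
  calls <- make_calls(c("A1", "A3", "B1", "B2", "A2"),
                      c(100, 150, 120, 130, 500),
                      c(200, 260, 240, 220, 800))
  region <- list(chrom = "chr1", start = 100, end = 260, cnv_type = "DEL")
  tabs <- carrier_tables(region, calls, ph)
  expect_equal(tabs$a, c(2, 1))   # A1, A3 in p1; B1 in p2 (B2 is a control)
  expect_equal(tabs$c, c(0, 1))
  expect_equal(tabs$a + tabs$b, c(3, 2))  # margins are the panel case counts
  # a DUP region ignores DEL calls entirely
  region$cnv_type <- "DUP"
  tabs <- carrier_tables(region, calls, ph)
  expect_equal(sum(tabs$a + tabs$c), 0)
})
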