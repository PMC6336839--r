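test_that("exact rank-sum p values match hand-derived tie enumerations", {
  # two tied non-zero donors among 9 cases vs 10 zero controls:
  # p(greater) = C(17,7)/C(19,9) = 36/171
  p <- wilcoxon_rank_sum(c(2, 2, rep(0, 7)), rep(0, 10),
                         alternative = "greater")
  expect_equal(p$p, 36 / 171, tolerance = 1e-12)
  expect_identical(p$method, "exact")
  # identical constant vectors are maximally unsurprising
  expect_equal(wilcoxon_rank_sum(rep(1, 4), rep(1, 4))$p, 1)
  # single most-extreme arrangement: 1/C(6,3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6),
                                 alternative = "less")$p, 0.05,
               tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact path agrees with the bitmask enumeration oracle (n <= 8, ties)", {
  set.seed(41)
  for (rep in 1:30) {
    nx <- sample(1:4, 1)
    ny <- sample(1:4, 1)
    pool <- sample(0:2, nx + ny, replace = TRUE) # heavy ties
    x <- pool[seq_len(nx)]
    y <- pool[nx + seq_len(ny)]
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_rank_sum(x, y, alternative = alt)$p,
                   oracle_wilcoxon(x, y, alternative = alt),
                   tolerance = 1e-12,
                   info = paste(alt, paste(x, collapse = ","), "|",
                                paste(y, collapse = ",")))
    }
  }
})

test_that("tie-free exact p values agree with the reference implementation", {
  set.seed(42)
  for (rep in 1:10) {
    x <- sample(1:100, 5)
    y <- sample(101:200, 6) - sample(0:80, 6)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_rank_sum(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  set.seed(43)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("published p-value column re-adjusts to the published FDR column", {
  p <- c(0.026, 0.026, 0.060, 0.060, 0.060, 0.145, 0.145, 1)
  adj <- bh_adjust(p)
  expect_equal(adj, c(rep(0.096, 5), rep(0.145 * 8 / 7, 2), 1),
               tolerance = 1e-12)
  expect_identical(round(adj, 3), c(rep(0.096, 5), 0.166, 0.166, 1))
})

test_that("bootstrap success is near-certain under separation, rare under the null", {
  sep <- bootstrap_success(seq(11, 30), seq(1, 10) / 10, B = 1000,
                           seed = 9)
  expect_gte(sep, 99)
  null <- bootstrap_success(rep(1, 10), rep(1, 10), B = 1000, seed = 9)
  expect_lte(null, 10)
  expect_identical(bootstrap_success(1:5, 2:6, B = 500, seed = 3),
                   bootstrap_success(1:5, 2:6, B = 500, seed = 3))
  expect_error(bootstrap_success(1, 1:5), "two donors")
  expect_error(bootstrap_success(1:5, 1:5, B = 10), "at least 100")
})

test_that("bootstrap success grows with the planted effect size", {
  set.seed(12)
  base <- rpois(10, 1)
  succ <- vapply(c(0, 2, 5), function(shift) {
    bootstrap_success(base + shift, base, B = 400, seed = 77)
  }, numeric(1))
  expect_true(all(diff(succ) >= 0))
})

test_that("odds ratios apply the zero-cell correction exactly when needed", {
  expect_equal(haldane_anscombe_or(2, 1, 1, 2), 4)
  expect_equal(haldane_anscombe_or(4, 19, 0, 7),
               (4.5 * 7.5) / (19.5 * 0.5), tolerance = 1e-12)
  expect_equal(haldane_anscombe_or(0, 23, 0, 7),
               (0.5 * 7.5) / (23.5 * 0.5), tolerance = 1e-12)
  expect_error(haldane_anscombe_or(-1, 1, 1, 1), "non-negative")
  # with all cells positive the correction branch never engages
  set.seed(44)
  for (rep in 1:20) {
    cells <- sample(1:30, 4, replace = TRUE)
    expect_equal(haldane_anscombe_or(cells[1], cells[2], cells[3],
                                     cells[4]),
                 (cells[1] * cells[4]) / (cells[2] * cells[3]))
  }
})

test_that("per-donor set counts pool both brain specimens of a donor", {
  cs <- read_final_callset()
  cohort <- read_final_cohort()
  counts <- per_individual_set_counts(
    cs, c("PMFBP1", "TEX15", "EP300", "OBSCN"), cohort)
  expect_identical(sum(counts$cases == 2), 2L) # two donors with 2 hits each
  expect_identical(unname(counts$cases[c("S7", "S9")]), c(2, 2))
  expect_true(all(counts$controls == 0))
  # the all-gene set recovers the full case burden
  all_counts <- per_individual_set_counts(cs, unique(cs$gene), cohort)
  expect_identical(sum(all_counts$cases), 25)
  expect_identical(sum(all_counts$controls), 7)
  empty <- per_individual_set_counts(cs, character(0), cohort)
  expect_true(all(c(empty$cases, empty$controls) == 0))
  orphan <- cs
  orphan$donor_id[1] <- "Z9"
  expect_error(per_individual_set_counts(orphan, "EP300", cohort),
               "unknown donor")
})

test_that("enrichment on the published call set reproduces the published overlaps", {
  cs <- read_final_callset()
  cohort <- read_final_cohort()
  sets <- published_genesets_standin()
  res <- run_enrichment(cs, sets, cohort, mode = "hypothesis_driven",
                        B = 200, seed = 5)
  pub <- read_enrichment_table()
  m <- match(pub$gene_set, res$gene_set)
  expect_false(anyNA(m))
  expect_identical(res$overlap_case[m], pub$overlap_case)
  expect_true(all(res$overlap_control[m] == 0L))
  expect_identical(res$set_size[m], pub$set_size)
  # BH family is exactly the eight tested sets
  expect_equal(res$fdr, bh_adjust(res$p_value), tolerance = 1e-12)
})

test_that("hypothesis-free mode drops sets outside the size window", {
  cs <- read_final_callset()
  cohort <- read_final_cohort()
  sets <- list(sets = list(small = c("EP300", "OBSCN"),
                           ok = c(cs$gene[1:5],
                                  sprintf("F%04d", 1:200)),
                           huge = sprintf("F%04d", 1:2000)),
               source = "hypothesis_free")
  res <- run_enrichment(cs, sets, cohort, mode = "hypothesis_free",
                        B = 100, seed = 1)
  expect_identical(res$gene_set, "ok")
  sets$sets <- sets$sets["small"]
  expect_error(run_enrichment(cs, sets, cohort, mode = "hypothesis_free",
                              B = 100, seed = 1), "no gene sets")
  noname <- cs
  noname$gene <- NA_character_
  expect_error(run_enrichment(noname, sets, cohort, B = 100, seed = 1),
               "gene annotations")
})
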