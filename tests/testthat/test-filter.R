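make_candidate <- function(pos = 2050L, chrom = "c2", specimen = "sp1",
                           ref = "C", alt = "T", pop_af = 0,
                           n_alleles = 2L, is_snv = TRUE,
                           depth = c(250L, 250L, 50L), mq = 55, bq = 33) {
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    specimen_id = specimen, is_snv = is_snv,
                    n_alleles = n_alleles, pop_af = pop_af,
                    stringsAsFactors = FALSE)
  tissues <- c("neuronal", "non_neuronal", "reference")
  for (i in seq_along(tissues)) {
    out[[paste0("depth_", tissues[i])]] <- depth[i]
    out[[paste0("mq_", tissues[i])]] <- mq
    out[[paste0("bq_", tissues[i])]] <- bq
  }
  out
}

test_that("consensus keeps only variants reported by both callers", {
  v <- function(pos, alt, caller, depth = 200L, ar = 8L) {
    data.frame(chrom = "1", pos = pos, ref = "C", alt = alt,
               specimen_id = "sp1", caller = caller, depth = depth,
               alt_reads = ar, vaf = ar / depth, is_snv = TRUE,
               stringsAsFactors = FALSE)
  }
  calls <- rbind(v(100, "T", "A"), v(200, "T", "A"),
                 v(200, "T", "B"), v(300, "T", "B"))
  cons <- consensus_intersect(calls)
  expect_identical(cons$pos, 200)
  # same site, different alternate allele is no consensus
  calls2 <- rbind(v(100, "T", "A"), v(100, "G", "B"))
  expect_identical(nrow(consensus_intersect(calls2)), 0L)
  # merged evidence comes from the deeper caller, both recorded
  calls3 <- rbind(v(100, "T", "A", depth = 150L, ar = 6L),
                  v(100, "T", "B", depth = 260L, ar = 9L))
  cons3 <- consensus_intersect(calls3)
  expect_identical(cons3$depth, 260L)
  expect_identical(cons3$alt_reads, 9L)
  expect_identical(cons3$depth_A, 150L)
  expect_identical(cons3$depth_B, 260L)
  # a specimen seen through one caller only = missing call set
  calls4 <- rbind(v(100, "T", "A"),
                  within(v(200, "T", "B"), specimen_id <- "sp2"))
  expect_error(consensus_intersect(calls4), "sp")
  # explicit caller labels allow legitimately empty per-specimen sets
  expect_identical(nrow(consensus_intersect(v(100, "T", "A"),
                                            callers = c("A", "B"))), 0L)
})

test_that("cascade thresholds are strict inequalities at every boundary", {
  targets <- tiny_targets()
  # depth exactly at the threshold in the reference tissue fails
  c1 <- make_candidate(depth = c(250L, 250L, 10L))
  r1 <- apply_cascade(c1, targets)
  expect_identical(nrow(r1$survivors), 0L)
  expect_identical(r1$report$first_fail, "depth")
  expect_identical(nrow(apply_cascade(make_candidate(
    depth = c(250L, 250L, 11L)), targets)$survivors), 1L)

  # two candidates 8 bp apart: both removed by the proximity rule
  c2 <- rbind(make_candidate(pos = 1100L, chrom = "c1"),
              make_candidate(pos = 1108L, chrom = "c1"))
  r2 <- apply_cascade(c2, targets)
  expect_identical(nrow(r2$survivors), 0L)
  expect_identical(r2$report$first_fail, c("proximity", "proximity"))
  # 11 bp apart passes (strict > 10)
  c3 <- rbind(make_candidate(pos = 1100L, chrom = "c1"),
              make_candidate(pos = 1111L, chrom = "c1"))
  expect_identical(nrow(apply_cascade(c3, targets)$survivors), 2L)

  # a population frequency of 1.48e-05 passes the < 0.001 rule
  expect_identical(nrow(apply_cascade(make_candidate(pop_af = 1.48e-05),
                                      targets)$survivors), 1L)
  expect_identical(nrow(apply_cascade(make_candidate(pop_af = 1e-3),
                                      targets)$survivors), 0L)

  # 349 bp outside the nearest target passes; 350 fails (strict < 350)
  # target c1:[1000,1150); base at pos0 = 1150+349-1 is 349 bp outside
  c349 <- make_candidate(pos = 1150L + 349L, chrom = "c1")
  c350 <- make_candidate(pos = 1150L + 350L, chrom = "c1")
  expect_identical(nrow(apply_cascade(c349, targets)$survivors), 1L)
  r350 <- apply_cascade(c350, targets)
  expect_identical(nrow(r350$survivors), 0L)
  expect_identical(r350$report$first_fail, "near_target")

  # indels and non-biallelic sites fail their dedicated rules
  expect_identical(apply_cascade(make_candidate(is_snv = FALSE),
                                 targets)$report$first_fail, "snv_only")
  expect_identical(apply_cascade(make_candidate(n_alleles = 3L),
                                 targets)$report$first_fail, "two_alleles")
})

test_that("cascade matches the brute-force predicate oracle on random instances", {
  targets <- tiny_targets()
  set.seed(99)
  for (rep in 1:40) {
    cand <- random_candidates(sample(1:50, 1), targets)
    got <- apply_cascade(cand, targets)
    want <- oracle_cascade(cand, targets)
    expect_identical(got$report$pass, want)
    expect_identical(nrow(got$survivors), sum(want))
    # ledger conservation: every candidate accounted for exactly once
    expect_identical(nrow(got$report), nrow(cand))
    expect_identical(sum(got$report$pass) +
                       sum(!is.na(got$report$first_fail)), nrow(cand))
  }
})

test_that("relaxing any single threshold never shrinks the survivor set", {
  targets <- tiny_targets()
  set.seed(123)
  base <- cascade_thresholds()
  relaxed <- list(
    cascade_thresholds(mq = 5), cascade_thresholds(bq = 5),
    cascade_thresholds(dp = 5), cascade_thresholds(proximity = 5),
    cascade_thresholds(target_dist = 1000),
    cascade_thresholds(max_af = 0.05))
  for (rep in 1:10) {
    cand <- random_candidates(40, targets)
    key <- function(s) paste(s$specimen_id, s$chrom, s$pos, s$alt)
    surv0 <- key(apply_cascade(cand, targets, base)$survivors)
    for (thr in relaxed) {
      surv1 <- key(apply_cascade(cand, targets, thr)$survivors)
      expect_true(all(surv0 %in% surv1))
    }
  }
})

test_that("outlier specimens are flagged by the robust count rule", {
  counts <- stats::setNames(c(rep(0:3, length.out = 18), 40L),
                            paste0("sp", 1:19))
  expect_identical(exclude_outlier_specimens(counts), "sp19")
  expect_identical(exclude_outlier_specimens(
    stats::setNames(rep(2L, 10), paste0("sp", 1:10))), character(0))
  expect_identical(exclude_outlier_specimens(counts, k_mad = Inf),
                   character(0))
  expect_warning(exclude_outlier_specimens(c(a = 1L, b = 2L)),
                 "fewer than 4")
})

test_that("genotype concordance flags swapped specimens and thin panels", {
  set.seed(8)
  sites <- sprintf("s%03d", 1:200)
  g <- stats::setNames(stats::rbinom(200, 2, 0.4), sites)
  near <- g
  flip <- sample(200, 2)
  near[flip] <- (near[flip] + 1) %% 3
  same <- genotype_concordance(list(a = g, b = near, c = g))
  expect_identical(same$flag, "ok")
  expect_true(all(same$pairs$concordance > 0.98))

  foreign <- stats::setNames(stats::rbinom(200, 2, 0.4), sites)
  swap <- genotype_concordance(list(neuronal = g, non_neuronal = near,
                                    reference = foreign))
  expect_identical(swap$flag, "mismatch")

  thin <- genotype_concordance(list(a = g[1:50], b = g[1:50]))
  expect_identical(thin$flag, "indeterminate")
})
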