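test_that("cohort skeleton matches the study design", {
  cfg <- sim_config(seed = 1)
  cohort <- simulate_cohort(cfg)
  expect_identical(nrow(cohort$donors), 19L)
  expect_identical(nrow(cohort$specimens), 57L)
  expect_identical(sum(cohort$donors$diagnosis == "case"), 9L)
  expect_identical(table(cohort$specimens$tissue)[["reference"]], 19L)
  expect_identical(length(cohort$risk_genes), 500L)
  expect_true(all(cohort$targets$end - cohort$targets$start == 150L))
})

test_that("config validation rejects out-of-range settings", {
  expect_error(sim_config(vaf_range = c(0.1, 0.05)), "vaf_range")
  expect_error(sim_config(caller_fp_rate = -1), "non-negative")
  expect_error(sim_config(signature_mixture = rep(1 / 95, 95)),
               "signature_mixture")
  expect_equal(sum(sim_config()$signature_mixture), 1, tolerance = 1e-12)
})

test_that("seeded simulation is bitwise reproducible", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$site_metrics, s2$site_metrics)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("planted counts, allele fractions and spectrum follow the config", {
  cfg <- sim_config(seed = 5)
  cohort <- simulate_cohort(cfg)
  # degenerate allele-fraction range pins every planted VAF
  cfg_fix <- sim_config(vaf_range = c(0.04, 0.04),
                        mean_somatic_per_case_specimen = 30, seed = 5)
  set.seed(5)
  v <- plant_somatic_variants("S01_neuronal", "neuronal", "case", cohort,
                              cfg_fix)
  expect_true(all(v$vaf == 0.04))
  expect_true(all(v$pos >= 1))
  expect_true(all(substr(v$context, 2, 2) == v$ref))
  expect_error(plant_somatic_variants("S01_reference", "reference",
                                      "case", cohort, cfg),
               "brain specimens")

  # shared_tissue_prob = 1 duplicates every case variant across tissues
  cfg_shared <- sim_config(shared_tissue_prob = 1, seed = 11)
  sim <- simulate_study(cfg_shared)
  expect_true(all(sim$truth$shared))
  per_site <- table(paste(sim$truth$donor_id, sim$truth$chrom,
                          sim$truth$pos))
  expect_true(all(per_site == 2))

  # total planted count lands inside the Poisson 99% envelope
  cfg_pois <- sim_config(seed = 21, shared_tissue_prob = 0,
                         mean_somatic_per_control_specimen = 0)
  simp <- simulate_study(cfg_pois)
  n_case_specimens <- 18
  lambda <- n_case_specimens * cfg_pois$mean_somatic_per_case_specimen
  expect_gte(nrow(simp$truth), stats::qpois(0.005, lambda))
  expect_lte(nrow(simp$truth), stats::qpois(0.995, lambda))

  # empirical spectrum converges to the configured mixture
  set.seed(31)
  big <- plant_somatic_variants(
    "S01_neuronal", "neuronal", "case", cohort,
    sim_config(mean_somatic_per_case_specimen = 10000, seed = 31))
  freq <- tabulate(context_channel(big$ref, big$alt, big$context),
                   nbins = 96) / nrow(big)
  tv <- 0.5 * sum(abs(freq - sim_config()$signature_mixture))
  expect_lt(tv, 0.05)

  # zero planting rates give an empty truth table
  none <- simulate_study(sim_config(mean_somatic_per_case_specimen = 0,
                                    mean_somatic_per_control_specimen = 0,
                                    caller_fp_rate = 0,
                                    shared_artifact_rate = 0, seed = 2))
  expect_identical(nrow(none$truth), 0L)
})

test_that("read evidence has the configured binomial structure", {
  cfg <- sim_config(seed = 6)
  set.seed(6)
  draws <- replicate(10000, {
    simulate_evidence(0.04, "neuronal", cfg)$alt_neuronal
  })
  expect_lt(abs(mean(draws) - 250 * 0.04), 0.5)
  # non-carrier tissues sit at the sequencing error rate
  set.seed(7)
  ref_alt <- replicate(4000, {
    ev <- simulate_evidence(0.04, "neuronal", cfg)
    ev$alt_reference
  })
  expect_lt(mean(ref_alt), 50 * 0.001 * 3 + 0.1)
  expect_gte(min(ref_alt), 0)
})

test_that("caller-private false positives die at consensus", {
  cfg <- sim_config(seed = 8, caller_dropout = 0,
                    shared_artifact_rate = 0)
  sim <- simulate_study(cfg)
  cons <- consensus_intersect(sim$calls,
                              callers = c("mutect_like", "strelka_like"))
  truth_key <- paste(sim$truth$specimen_id, sim$truth$chrom,
                     sim$truth$pos, sim$truth$alt)
  cons_key <- paste(cons$specimen_id, cons$chrom, cons$pos, cons$alt)
  # consensus = variants detected by both callers; with dropout 0 that is
  # exactly the truth rows above the sensitivity threshold
  detected <- truth_key[sim$truth$detected_mutect_like &
                          sim$truth$detected_strelka_like]
  expect_setequal(cons_key, detected)
  # and no caller-private false positive sneaks through
  fp_keys <- setdiff(paste(sim$calls$specimen_id, sim$calls$chrom,
                           sim$calls$pos, sim$calls$alt), truth_key)
  expect_length(intersect(cons_key, fp_keys), 0L)
})
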