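# shared helper: balanced two-specimen-per-donor cohort with a planted
# diagnosis effect, used across the mixed-model tests
sim_burden_data <- function(n_donors = 20, delta = 0, sd_donor = 1,
                            sd_resid = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  donor <- rep(sprintf("d%02d", seq_len(n_donors)), each = 2)
  diagnosis <- rep(rep(c("control", "case"), each = n_donors / 2), each = 2)
  cell <- rep(c("neuronal", "non_neuronal"), n_donors)
  sex <- rep(sample(c("male", "female"), n_donors, replace = TRUE),
             each = 2)
  u <- stats::rnorm(n_donors, 0, sd_donor)
  y <- 1 + delta * (diagnosis == "case") +
    u[as.integer(factor(donor))] + stats::rnorm(2 * n_donors, 0, sd_resid)
  data.frame(donor_id = donor, diagnosis = diagnosis, cell_type = cell,
             sex = sex, y = y, stringsAsFactors = FALSE)
}

fit_sim <- function(dat) {
  dat$diagnosis <- factor(dat$diagnosis, levels = c("control", "case"))
  dat$cell_type <- factor(dat$cell_type,
                          levels = c("neuronal", "non_neuronal"))
  X <- stats::model.matrix(~ diagnosis * cell_type + sex, dat)
  fit_lmm(dat$y, X, dat$donor_id)
}

test_that("burden table counts survivors per specimen and class", {
  cs <- read_final_callset()
  cohort <- read_final_cohort()
  specimens <- data.frame(
    specimen_id = paste(rep(cohort$donor_id, each = 2),
                        c("neuronal", "non_neuronal"), sep = "_"),
    donor_id = rep(cohort$donor_id, each = 2),
    tissue = rep(c("neuronal", "non_neuronal"), nrow(cohort)),
    excluded = FALSE, exclude_reason = "", stringsAsFactors = FALSE)
  tab <- build_burden_table(cs, specimens, cohort)
  expect_identical(nrow(tab), 38L)
  expect_identical(sum(tab$count_all[tab$diagnosis == "case"]), 25L)
  expect_identical(sum(tab$count_all[tab$diagnosis == "control"]), 7L)
  expect_identical(sum(tab$count_ns_lof[tab$diagnosis == "case"]), 12L)
  expect_identical(sum(tab$count_ns_lof[tab$diagnosis == "control"]), 5L)
  expect_true(all(tab$count_all >= tab$count_ns_lof))
  # empty survivor set gives an all-zero table
  tab0 <- build_burden_table(cs[0, ], specimens, cohort)
  expect_true(all(tab0$count_all == 0L))
  # survivors naming unknown specimens are rejected
  bad <- cs
  bad$specimen_id[1] <- "nobody_neuronal"
  expect_error(build_burden_table(bad, specimens, cohort), "nobody")
})

test_that("group rates divide counts by group donor totals", {
  burden <- data.frame(diagnosis = c("case", "case", "control"),
                       count_all = c(20L, 5L, 7L),
                       count_ns_lof = c(10L, 2L, 5L))
  donors <- data.frame(donor_id = sprintf("d%d", 1:19),
                       diagnosis = rep(c("case", "control"), c(9, 10)))
  expect_equal(group_rate(burden, donors, "case", "all"), 25 / 9)
  expect_equal(group_rate(burden, donors, "control", "all"), 0.7)
  expect_equal(group_rate(burden, donors, "case", "ns_lof"), 12 / 9)
  burden0 <- burden
  burden0$count_all <- 0L
  expect_identical(group_rate(burden0, donors, "case", "all"), 0)
  expect_error(group_rate(burden, donors[donors$diagnosis == "case", ],
                          "control", "all"), "no donors")
})

test_that("REML fit reduces to OLS when donor variance is zero", {
  set.seed(2)
  dat <- sim_burden_data(n_donors = 16, sd_donor = 0, seed = 2)
  # remove all between-donor variation so the REML estimate sits exactly
  # at the boundary (donor means of the noise are identically zero)
  e <- dat$y - stats::ave(dat$y, dat$donor_id)
  dat$y <- 1 + 2 * (dat$diagnosis == "case") + e
  fit <- fit_sim(dat)
  expect_true(fit$singular)
  ols <- stats::lm(y ~ diagnosis * cell_type + sex,
                   transform_factors <- within(dat, {
                     diagnosis <- factor(diagnosis,
                                         levels = c("control", "case"))
                     cell_type <- factor(cell_type,
                                         levels = c("neuronal",
                                                    "non_neuronal"))
                   }))
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
  # Satterthwaite df collapse to the OLS residual df at the boundary
  expect_equal(fit$coefficients$df,
               rep(stats::df.residual(ols), nrow(fit$coefficients)),
               tolerance = 1e-3)
})

test_that("REML/Satterthwaite agrees with an independent mixed-model fit", {
  skip_if_not_installed("lmerTest")
  for (seed in 1:5) {
    dat <- sim_burden_data(n_donors = 14, delta = 1.5, sd_donor = 1.1,
                           sd_resid = 0.9, seed = 100 + seed)
    mine <- fit_sim(dat)
    ref <- lmerTest::lmer(
      y ~ diagnosis * cell_type + sex + (1 | donor_id),
      data = within(dat, {
        diagnosis <- factor(diagnosis, levels = c("control", "case"))
        cell_type <- factor(cell_type,
                            levels = c("neuronal", "non_neuronal"))
      }))
    sm <- summary(ref)$coefficients
    expect_equal(mine$coefficients$estimate, unname(sm[, "Estimate"]),
                 tolerance = 1e-4)
    expect_equal(mine$coefficients$se, unname(sm[, "Std. Error"]),
                 tolerance = 1e-4)
    expect_true(max(abs(mine$coefficients$df - sm[, "df"])) < 0.5)
  }
})

test_that("Satterthwaite df stay in range and approach OLS df as donor variance shrinks", {
  dat <- sim_burden_data(n_donors = 16, sd_donor = 1.5, seed = 55)
  dat$diagnosis <- factor(dat$diagnosis, levels = c("control", "case"))
  dat$cell_type <- factor(dat$cell_type,
                          levels = c("neuronal", "non_neuronal"))
  X <- stats::model.matrix(~ diagnosis * cell_type + sex, dat)
  df_resid <- nrow(X) - ncol(X)
  # shrink the donor effect toward zero while keeping the noise fixed
  set.seed(55)
  u <- stats::rnorm(16, 0, 1)
  e <- stats::rnorm(32, 0, 1)
  df_diag <- vapply(c(2, 0.5, 0.05), function(s) {
    y <- 1 + s * u[as.integer(factor(dat$donor_id))] + e
    fit <- fit_lmm(y, X, dat$donor_id)
    expect_true(all(fit$coefficients$df > 0))
    fit$coefficients$df[2]
  }, numeric(1))
  expect_true(all(diff(abs(df_diag - df_resid)) <= 1e-6))
})

test_that("the burden model recovers a planted diagnosis effect", {
  set.seed(77)
  ests <- replicate(50, {
    dat <- sim_burden_data(n_donors = 20, delta = 2)
    fit_sim(dat)$coefficients$estimate[2]
  })
  expect_lt(abs(mean(ests) - 2), 0.15)
})

test_that("fit_burden_lmm builds the study design matrix and flags tiny groups", {
  set.seed(3)
  dat <- sim_burden_data(n_donors = 12, delta = 1, seed = 3)
  dat$count_all <- pmax(0L, as.integer(round(dat$y)))
  dat$count_ns_lof <- pmin(dat$count_all, 1L)
  dat$specimen_id <- paste(dat$donor_id, dat$cell_type, sep = "_")
  fit <- fit_burden_lmm(dat, "count_all")
  expect_s3_class(fit, "mosaic_lmm")
  expect_setequal(fit$coefficients$term,
                  c("(Intercept)", "diagnosiscase",
                    "cell_typenon_neuronal", "sexmale",
                    "diagnosiscase:cell_typenon_neuronal"))
  one_group <- dat[dat$diagnosis == "case", ]
  expect_error(fit_burden_lmm(one_group, "count_all"), "two donors")
})

test_that("allele-fraction comparison handles typical and degenerate input", {
  # identical distributions
  same <- vaf_group_test(c(0.02, 0.03, 0.05, 0.02, 0.03, 0.05),
                         rep(c("case", "control"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # hard separation: closed-form Welch limit
  sep <- vaf_group_test(c(rep(0.10, 10), rep(0.02, 10)),
                        rep(c("case", "control"), each = 10))
  expect_lt(sep$p, 1e-6)
  expect_error(vaf_group_test(c(0.1, 0.2, 0.3), c("case", "case", "control")),
               "two allele fractions")
  # near-separation with noise: still strongly significant
  set.seed(4)
  noisy <- vaf_group_test(c(stats::rnorm(10, 0.10, 0.002),
                            stats::rnorm(10, 0.02, 0.002)),
                          rep(c("case", "control"), each = 10))
  expect_lt(noisy$p, 1e-6)
})

test_that("allele-fraction summary returns mean and range", {
  s <- summarize_vaf(c(0.02, 0.06))
  expect_equal(s$mean, 0.04)
  expect_equal(s$min, 0.02)
  expect_equal(s$max, 0.06)
  one <- summarize_vaf(0.05)
  expect_equal(unlist(one), c(mean = 0.05, min = 0.05, max = 0.05))
  expect_error(summarize_vaf(numeric(0)), "no allele fractions")
})
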