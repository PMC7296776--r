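test_that("covariate sampling is deterministic, bounded and matches marginals", {
  expect_equal(nrow(sample_covariates(0)), 0)
  a <- sample_covariates(500, seed = 3)
  b <- sample_covariates(500, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$psa > 0 & a$psa < 100))
  expect_true(all(!a$metastatic))
  expect_true(all(is.na(a$conservative_subtype) |
                    a$treatment == "conservative"))

  m <- covariate_marginals()
  big <- sample_covariates(50000, seed = 9)
  for (var in c("grade_group", "t_stage", "treatment")) {
    p <- m[[var]]
    lev <- switch(var, grade_group = 1:5,
                  t_stage = c("T1", "T2", "T3", "T4"),
                  treatment = c("conservative", "prostatectomy",
                                "radiotherapy", "adt"))
    freq <- as.numeric(table(factor(big[[var]], levels = lev))) / 50000
    se <- sqrt(p * (1 - p) / 50000)
    expect_true(all(abs(freq - p) <= 3 * se + 1e-12),
                info = paste("marginal drift in", var))
  }
  expect_lt(abs(mean(big$comorbid) - m$comorbid),
            3 * sqrt(m$comorbid * (1 - m$comorbid) / 50000))
  expect_lt(abs(mean(big$age_dx) - m$age_mean), 0.2)
  expect_error(covariate_marginals(grade_group = c(0.5, 0.5, 0, 0, 0.1)),
               "probability")
})

test_that("outcome simulation respects limiting cases", {
  recs <- sample_covariates(400, seed = 5)
  none <- simulate_outcomes(recs, true_model(const_coefs(0, 0)), seed = 5)
  expect_true(all(none$event == "censored"))
  # overwhelming cancer hazard, no other-cause deaths
  coefs_pc <- const_coefs(h_pc = 100, h_npc = 0, radical_hr_pc = 1)
  all_pc <- simulate_outcomes(recs, true_model(coefs_pc), seed = 5)
  expect_gte(mean(all_pc$event == "pca_death"), 0.99)
  expect_error(
    simulate_outcomes(recs, true_model(const_coefs(0.02, 0.02)), seed = "x"))
})

test_that("uncensored symmetric simulation matches the closed-form CIF", {
  n <- 20000
  recs <- sample_covariates(n, seed = 11)
  truth <- true_model(const_coefs(h_pc = 0.02, h_npc = 0.02),
                      admin_censor_date = as.Date("2400-01-01"))
  sim <- simulate_outcomes(recs, truth, seed = 11)
  target <- (1 - exp(-0.4)) / 2          # 10-year CIF of each cause
  se <- sqrt(target * (1 - target) / n)
  emp_pc <- mean(sim$event == "pca_death" & sim$followup_years <= 10)
  emp_npc <- mean(sim$event == "other_death" & sim$followup_years <= 10)
  expect_lt(abs(emp_pc - target), 3 * se)
  expect_lt(abs(emp_npc - target), 3 * se)
})

test_that("simulator and risk engine agree under the benchmark truth", {
  # central self-consistency: empirical cause-specific incidence on an
  # uncensored simulation matches the engine's analytic mean CIF
  n <- 30000
  recs <- sample_covariates(n, seed = 17)
  truth <- true_model(admin_censor_date = as.Date("2400-01-01"))
  sim <- simulate_outcomes(recs, truth, seed = 17)
  preds <- predict_cohort(recs, truth$coefs)$scenarios$as_treated
  for (t in c(5, 10, 15)) {
    for (cause in c("pca_death", "other_death")) {
      mat <- if (cause == "pca_death") preds$cif_pc else preds$cif_npc
      analytic <- mean(mat[, t])
      emp <- mean(sim$event == cause & sim$followup_years <= t)
      se <- sqrt(analytic * (1 - analytic) / n)
      expect_lt(abs(emp - analytic), 3 * se)
    }
  }
})

test_that("random streams are independent: censoring changes leave latent times alone", {
  recs <- sample_covariates(300, seed = 23)
  co <- const_coefs(h_pc = 0.05, h_npc = 0.05)
  early <- simulate_outcomes(recs, true_model(
    co, admin_censor_date = as.Date("2012-12-31"),
    accrual_end = as.Date("2010-12-31")), seed = 23)
  late <- simulate_outcomes(recs, true_model(
    co, admin_censor_date = as.Date("2030-12-31"),
    accrual_end = as.Date("2010-12-31")), seed = 23)
  died_both <- early$event != "censored" & late$event != "censored"
  expect_true(any(died_both))
  expect_equal(early$followup_years[died_both],
               late$followup_years[died_both])
  expect_equal(early$dx_date, late$dx_date)
})

test_that("benchmark cohort reproduces the registry's headline structure", {
  b <- make_benchmark_cohort(20000, seed = 1)
  s <- summarize_cohort(b$cohort)
  expect_gte(s$median_followup, 12)
  expect_lte(s$median_followup, 15)
  expect_lt(abs(s$crude_pcsm_rate - 1.38), 0.25)
  expect_lt(abs(s$crude_acm_rate - 4.43), 0.5)
  # byte-identical CSV on re-run with the same seed
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_cohort_csv(b$cohort, p1)
  write_cohort_csv(make_benchmark_cohort(20000, seed = 1)$cohort, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
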