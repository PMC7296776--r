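test_that("inclusion filters retain clean records and log every exclusion", {
  recs <- do.call(rbind, list(
    toy_record("p1"), toy_record("p2"), toy_record("p3"),
    toy_record("p4", psa = 150),
    toy_record("p5", metastatic = TRUE),
    toy_record("p6", gg = NA)))
  res <- apply_inclusion_filters(patient_records(recs))
  expect_equal(res$log$n_retained, 3)
  expect_equal(res$log$n_excluded, 3)
  expect_setequal(res$cohort$patient_id, c("p1", "p2", "p3"))
  expect_setequal(res$log$excluded_ids, c("p4", "p5", "p6"))
  expect_equal(unname(res$log$reasons[["psa_out_of_range"]]), 1)
  expect_equal(unname(res$log$reasons[["metastatic"]]), 1)
  expect_equal(unname(res$log$missing_fields[["grade_group"]]), 1)
  expect_equal(res$log$excluded_pct, 50.0)
})

test_that("filtering is idempotent and empty input is handled", {
  empty <- apply_inclusion_filters(patient_records(
    data.frame(patient_id = character(0))))
  expect_equal(nrow(empty$cohort), 0)
  expect_equal(empty$log$n_excluded, 0)

  recs <- patient_records(rbind(toy_record("a"), toy_record("b", psa = 200)))
  once <- apply_inclusion_filters(recs)
  twice <- apply_inclusion_filters(once$cohort)
  expect_equal(as.data.frame(twice$cohort), as.data.frame(once$cohort))
  expect_equal(twice$log$n_excluded, 0)
})

test_that("a record missing several fields is excluded once with per-field tallies", {
  recs <- rbind(toy_record("m1", psa = NA, gg = NA),
                toy_record("m2", psa = NA),
                toy_record("ok"))
  res <- apply_inclusion_filters(patient_records(recs))
  expect_equal(res$log$n_excluded, 2)
  expect_equal(unname(res$log$missing_fields[["psa"]]), 2)
  expect_equal(unname(res$log$missing_fields[["grade_group"]]), 1)
})

test_that("missing metastatic status is excluded unless the M0 flag is set", {
  recs <- patient_records(rbind(toy_record("u", metastatic = NA),
                                toy_record("v")))
  strict <- apply_inclusion_filters(recs)
  expect_equal(strict$log$n_retained, 1)
  lenient <- apply_inclusion_filters(
    recs, inclusion_criteria(missing_m_as_m0 = TRUE))
  expect_equal(lenient$log$n_retained, 2)
  expect_true(lenient$log$missing_m_as_m0)
})

test_that("PSA filter is strictly < 100 and the window is inclusive", {
  recs <- patient_records(rbind(
    toy_record("at_limit", psa = 100),
    toy_record("below", psa = 99.99),
    toy_record("win_lo", dx_date = as.Date("2000-01-01")),
    toy_record("win_hi", dx_date = as.Date("2010-12-31")),
    toy_record("late", dx_date = as.Date("2011-01-01"))))
  res <- apply_inclusion_filters(recs)
  expect_setequal(res$cohort$patient_id,
                  c("below", "win_lo", "win_hi"))
})

test_that("treatment groups partition the cohort; radical pools surgery and radiotherapy", {
  cohort <- toy_cohort(toy_record("c1"),
                       toy_record("r1", treatment = "prostatectomy"),
                       toy_record("r2", treatment = "radiotherapy"),
                       toy_record("a1", treatment = "adt"))
  grp <- assign_treatment_groups(cohort)
  expect_equal(unname(grp[c("r1", "r2")]), c("radical", "radical"))
  expect_equal(sort(unique(unname(grp))), c("adt", "conservative", "radical"))
  expect_equal(length(grp), nrow(cohort))  # partition: one group each

  all_cons <- toy_cohort(toy_record("c1"), toy_record("c2"))
  expect_false("radical" %in% assign_treatment_groups(all_cons))

  bad <- all_cons
  bad$treatment[1] <- NA
  expect_error(assign_treatment_groups(bad), "missing treatment")
})

test_that("cohort summary computes rates, truncated counts and percentages", {
  cohort <- toy_cohort(
    toy_record("d1", fu = 4, event = "pca_death",
               treatment = "prostatectomy"),
    toy_record("d2", fu = 12, event = "other_death"),
    toy_record("c1", fu = 8, event = "censored", comorbid = TRUE),
    toy_record("c2", fu = 16, event = "censored", gg = 3))
  s <- summarize_cohort(cohort)
  expect_equal(s$person_years, 40)
  expect_equal(unname(s$events[["any_death"]]), 2)
  # 10-year truncation keeps only the death at 4 years
  expect_equal(unname(s$events_10y[["pca_death"]]), 1)
  expect_equal(unname(s$events_10y[["any_death"]]), 1)
  # raw rate recovers the count exactly before rounding
  expect_equal(s$rates_raw[["pcsm"]] * s$person_years / 100, 1)
  expect_equal(s$crude_pcsm_rate, 2.5)
  expect_equal(s$crude_acm_rate, 5)
  for (d in s$distributions) {
    expect_lt(abs(sum(d$pct) - 100), 0.2)
  }

  none <- toy_cohort(toy_record("x", fu = 5), toy_record("y", fu = 5))
  s0 <- summarize_cohort(none)
  expect_equal(s0$crude_pcsm_rate, 0)
  expect_equal(s0$crude_acm_rate, 0)

  zero_py <- toy_cohort(toy_record("z", fu = 0))
  expect_error(summarize_cohort(zero_py), "person-years")
})

test_that("record validation enforces invariants", {
  expect_error(patient_records(data.frame(patient_id = "a", ppc = 1.5)),
               "ppc")
  expect_error(patient_records(data.frame(patient_id = "a",
                                          followup_years = -1)),
               "followup_years")
  expect_error(patient_records(data.frame(patient_id = "a", event = "dead")),
               "invalid event")
  expect_error(patient_records(
    data.frame(patient_id = "a", treatment = "adt",
               conservative_subtype = "watchful_waiting")),
    "conservative_subtype")
  expect_error(patient_records(data.frame(patient_id = c("a", "a"))),
               "duplicate")
})
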