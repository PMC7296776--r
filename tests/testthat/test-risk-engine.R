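test_that("prognostic index is the transformed linear combination", {
  rec <- toy_cohort(toy_record("a", age = 70, psa = 10))
  co <- const_coefs(betas_pc = c(age_c = 0.1, lpsa = 0.5))
  expect_equal(prognostic_index(rec, co, "pc"), 0.1 * 5 + 0.5 * log(10),
               tolerance = 1e-12)
  # all betas zero
  expect_equal(prognostic_index(rec, const_coefs(), "pc"), 0)
  # linearity: doubling a beta doubles the term contribution
  co2 <- const_coefs(betas_pc = c(age_c = 0.2, lpsa = 0.5))
  expect_equal(prognostic_index(rec, co2, "pc") -
                 prognostic_index(rec, co, "pc"), 0.1 * 5)
})

test_that("missing required covariates are reported by name and patient", {
  rec <- toy_cohort(toy_record("px", age = NA))
  co <- const_coefs(betas_pc = c(age_c = 0.1))
  expect_error(prognostic_index(rec, co, "pc"), "age_dx.*px")
})

test_that("ppc modes: excluded tolerates missing, others encode as declared", {
  co_cont <- const_coefs(betas_pc = c(ppc = 1), ppc_mode = "continuous")
  co_dich <- const_coefs(betas_pc = c(ppc = 1), ppc_mode = "dichotomous_50")
  co_excl <- const_coefs(betas_pc = c(ppc = 1), ppc_mode = "excluded")
  rec <- toy_cohort(toy_record("a", ppc = 0.6))
  expect_equal(prognostic_index(rec, co_cont, "pc"), 0.6)
  expect_equal(prognostic_index(rec, co_dich, "pc"), 1)
  expect_equal(prognostic_index(toy_cohort(toy_record("a", ppc = 0.4)),
                                co_dich, "pc"), 0)
  missing_ppc <- toy_cohort(toy_record("m"))
  expect_equal(prognostic_index(missing_ppc, co_excl, "pc"), 0)
  expect_error(prognostic_index(missing_ppc, co_cont, "pc"), "ppc")
})

test_that("cumulative incidence matches single-cause and symmetric closed forms", {
  t <- 1:15
  # all hazards zero
  p0 <- cumulative_incidence(toy_cohort(toy_record("a")),
                             const_coefs(h_pc = 0, h_npc = 0))
  expect_equal(p0$as_treated$cif_pc, rep(0, 15))
  expect_equal(p0$as_treated$surv, rep(1, 15))
  # single cause: CIF_pc(t) = 1 - exp(-h t)
  h <- 0.07
  p1 <- cumulative_incidence(toy_cohort(toy_record("a")),
                             const_coefs(h_pc = h, h_npc = 0))
  expect_equal(p1$as_treated$cif_pc, 1 - exp(-h * t), tolerance = 1e-9)
  expect_equal(p1$as_treated$cif_npc, rep(0, 15))
  # symmetric two-cause: each CIF = (1 - exp(-2 h t)) / 2
  p2 <- cumulative_incidence(toy_cohort(toy_record("a")),
                             const_coefs(h_pc = h, h_npc = h))
  expect_equal(p2$as_treated$cif_pc, (1 - exp(-2 * h * t)) / 2,
               tolerance = 1e-9)
  expect_equal(p2$as_treated$cif_npc, p2$as_treated$cif_pc)
})

test_that("conservation and monotonicity hold for random configurations", {
  set.seed(421)
  for (rep in 1:20) {
    co <- coefficient_set(
      betas = list(pc = c(age_c = rnorm(1, 0, 0.05),
                          lpsa = rnorm(1, 0, 0.3)),
                   npc = c(age_c = rnorm(1, 0.05, 0.03))),
      transforms = list(
        age_c = list(variable = "age_dx", type = "identity", center = 65),
        lpsa = list(variable = "psa", type = "log", center = log(10))),
      baseline_hazard = list(pc = runif(15, 0, 0.05),
                             npc = runif(15, 0, 0.05)),
      radical_hr_pc = runif(1, 0.3, 1.5))
    rec <- toy_cohort(toy_record("a", age = runif(1, 45, 90),
                                 psa = runif(1, 0.5, 99)))
    p <- cumulative_incidence(rec, co)
    for (sc in c("as_treated", "conservative", "radical")) {
      s <- p[[sc]]
      expect_lt(max(abs(s$cif_pc + s$cif_npc + s$surv - 1)), 1e-9)
      expect_true(all(diff(s$cif_pc) >= -1e-12))
      expect_true(all(diff(s$cif_npc) >= -1e-12))
      expect_true(all(diff(s$surv) <= 1e-12))
      expect_true(all(s$cif_pc >= 0 & s$cif_pc <= 1 & s$surv >= 0))
    }
  }
})

test_that("treatment scenarios are coherent across the cohort", {
  cohort <- toy_cohort(toy_record("c", treatment = "conservative"),
                       toy_record("r", treatment = "prostatectomy"),
                       toy_record("x", treatment = "radiotherapy"),
                       toy_record("h", treatment = "adt"))
  co <- const_coefs(h_pc = 0.05, h_npc = 0.02, radical_hr_pc = 0.6)
  p <- predict_cohort(cohort, co)
  at <- p$scenarios$as_treated
  cons <- p$scenarios$conservative
  rad <- p$scenarios$radical
  expect_equal(at$cif_pc[1, ], cons$cif_pc[1, ])   # conservative patient
  expect_equal(at$cif_pc[2, ], rad$cif_pc[2, ])    # prostatectomy
  expect_equal(at$cif_pc[3, ], rad$cif_pc[3, ])    # radiotherapy
  expect_equal(at$cif_pc[4, ], cons$cif_pc[4, ])   # adt with hr 1 default
  # hr < 1: radical ACM never exceeds conservative ACM
  expect_true(all(1 - rad$surv <= 1 - cons$surv + 1e-12))
  # hr = 1: scenarios identical, treatment benefit 0
  co1 <- const_coefs(h_pc = 0.05, h_npc = 0.02, radical_hr_pc = 1)
  p1 <- cumulative_incidence(cohort[1, ], co1)
  expect_equal(p1$treatment_benefit, rep(0, 15))
  # single-patient prediction equals the direct call
  single <- cumulative_incidence(cohort[2, ], co)
  expect_equal(single$as_treated$cif_pc, at$cif_pc[2, ])
})

test_that("ADT multiplier shifts only the as-treated cancer hazard of ADT men", {
  cohort <- toy_cohort(toy_record("h", treatment = "adt"),
                       toy_record("c", treatment = "conservative"))
  co_hi <- const_coefs(h_pc = 0.05, h_npc = 0.02, adt_hr_pc = 1.5)
  co_1 <- const_coefs(h_pc = 0.05, h_npc = 0.02, adt_hr_pc = 1)
  p_hi <- predict_cohort(cohort, co_hi)$scenarios$as_treated
  p_1 <- predict_cohort(cohort, co_1)$scenarios$as_treated
  expect_gt(p_hi$cif_pc[1, 15], p_1$cif_pc[1, 15])
  expect_equal(p_hi$cif_pc[2, ], p_1$cif_pc[2, ])
})

test_that("competing-risk crowd-out: raising a cancer beta lowers the other cause's CIF", {
  rec <- toy_cohort(toy_record("a", gg = 5))
  lo <- const_coefs(h_pc = 0.03, h_npc = 0.03,
                    betas_pc = c(gg5 = 0.0))
  hi <- const_coefs(h_pc = 0.03, h_npc = 0.03,
                    betas_pc = c(gg5 = 1.0))
  p_lo <- cumulative_incidence(rec, lo)$as_treated
  p_hi <- cumulative_incidence(rec, hi)$as_treated
  expect_gt(p_hi$cif_pc[15], p_lo$cif_pc[15])
  expect_lt(p_hi$cif_npc[15], p_lo$cif_npc[15])
})

test_that("expected events sum interpolated per-patient risks", {
  h <- 0.05
  co <- const_coefs(h_pc = h, h_npc = 0)
  cif <- function(t) 1 - exp(-h * t)   # closed form at integer years
  interp <- function(t) {              # chord between annual grid points
    u0 <- floor(t); cif(u0) + (t - u0) * (cif(u0 + 1) - cif(u0))
  }
  cohort <- toy_cohort(toy_record("a", fu = 3),
                       toy_record("b", fu = 7.5),
                       toy_record("c", fu = 20))
  ee <- expected_events(cohort, co)
  expect_equal(ee$E_pc, cif(3) + interp(7.5) + cif(15), tolerance = 1e-12)
  expect_equal(ee$E_acm, ee$E_pc, tolerance = 1e-12)
  expect_equal(ee$E_npc, 0)
  # zero follow-up contributes zero everywhere
  zero <- toy_cohort(toy_record("z", fu = 0))
  expect_equal(expected_events(zero, co)$E_acm, 0)
  # single patient: contribution equals the total
  one <- toy_cohort(toy_record("o", fu = 4))
  e1 <- expected_events(one, co)
  expect_equal(e1$contributions$e_pc, e1$E_pc)
  bad <- one
  bad$followup_years <- -2
  expect_error(expected_events(bad, co), "negative|followup")
})

test_that("coefficient sets validate structure and round-trip through JSON", {
  expect_error(const_coefs(h_pc = -0.01), "non-negative")
  expect_error(coefficient_set(betas = list(pc = c(x = 1), npc = c()),
                               transforms = list(),
                               baseline_hazard = list(pc = rep(0, 15),
                                                      npc = rep(0, 15))),
               "transform")
  expect_error(coefficient_set(betas = list(pc = c(), npc = c()),
                               transforms = list(),
                               baseline_hazard = list(pc = rep(0, 10),
                                                      npc = rep(0, 15))),
               "15")
  co <- illustrative_coefficients()
  path <- tempfile(fileext = ".json")
  write_coefficients(co, path)
  co2 <- read_coefficients(path)
  expect_equal(co2$betas, co$betas)
  expect_equal(co2$baseline_hazard$pc, co$baseline_hazard$pc)
  expect_equal(co2$radical_hr_pc, co$radical_hr_pc)
  rec <- toy_cohort(toy_record("a", gg = 3, t_stage = "T2"))
  expect_equal(prognostic_index(rec, co2, "pc"),
               prognostic_index(rec, co, "pc"))
})
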