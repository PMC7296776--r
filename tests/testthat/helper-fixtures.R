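# Shared fixtures and independent oracles, built in code at test time.

# A fully specified clean record; override fields as needed.
toy_record <- function(id = "A", age = 65, psa = 10, t_stage = "T1",
                       gg = 1, ppc = NA, treatment = "conservative",
                       subtype = NA, comorbid = FALSE, metastatic = FALSE,
                       dx_date = as.Date("2005-06-01"), fu = 10,
                       event = "censored") {
  data.frame(patient_id = id, age_dx = age, psa = psa, t_stage = t_stage,
             grade_group = gg, ppc = ppc, treatment = treatment,
             conservative_subtype = subtype, comorbid = comorbid,
             metastatic = metastatic, dx_date = dx_date,
             followup_years = fu, event = event, stringsAsFactors = FALSE)
}

toy_cohort <- function(...) {
  rows <- list(...)
  patient_records(do.call(rbind, rows))
}

# Coefficient set with constant hazards and optional single beta terms.
const_coefs <- function(h_pc = 0.02, h_npc = 0.02, radical_hr_pc = 1,
                        betas_pc = c(), betas_npc = c(),
                        transforms = list(), ppc_mode = "excluded",
                        adt_hr_pc = 1) {
  base_tr <- list(
    age_c = list(variable = "age_dx", type = "identity", center = 65),
    lpsa = list(variable = "psa", type = "log", center = 0),
    gg5 = list(variable = "grade_group", type = "indicator", level = 5),
    comorb = list(variable = "comorbid", type = "indicator", level = TRUE),
    ppc = list(variable = "ppc", type = "ppc"))
  coefficient_set(
    betas = list(pc = betas_pc, npc = betas_npc),
    transforms = utils::modifyList(base_tr, transforms),
    baseline_hazard = list(pc = rep(h_pc, 15), npc = rep(h_npc, 15)),
    radical_hr_pc = radical_hr_pc, ppc_mode = ppc_mode,
    adt_hr_pc = adt_hr_pc)
}

# Exhaustive O(n^2) concordance oracle, independent of the C++ kernel.
bf_concordance <- function(score, time, event) {
  n <- length(score)
  C <- D <- Tt <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- NA
      if (time[i] < time[j] && event[i]) { a <- i; b <- j }
      else if (time[j] < time[i] && event[j]) { a <- j; b <- i }
      else if (time[i] == time[j]) {
        if (event[i] && !event[j]) { a <- i; b <- j }
        else if (event[j] && !event[i]) { a <- j; b <- i }
      }
      if (is.na(a)) next
      if (score[a] > score[b]) C <- C + 1
      else if (score[a] < score[b]) D <- D + 1
      else Tt <- Tt + 1
    }
  }
  P <- C + D + Tt
  list(c = if (P > 0) (C + 0.5 * Tt) / P else NA_real_, comparable = P,
       tied = Tt)
}

# Random censored survival fixture for concordance tests.
random_surv_fixture <- function(n, seed, tie_scores = FALSE) {
  set.seed(seed)
  score <- if (tie_scores) round(runif(n), 1) else runif(n)
  time <- rexp(n, rate = 0.2 + score)
  cens <- rexp(n, rate = 0.2)
  list(score = score, time = pmin(time, cens), event = time <= cens)
}
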