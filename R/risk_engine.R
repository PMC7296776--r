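#' Prognostic index (linear predictor) for one cause
#'
#' Evaluates the linear combination of transformed covariates and beta
#' coefficients on the log-hazard scale for the requested cause.  Terms are
#' evaluated after their declared transforms (centering, natural log,
#' category indicators, biopsy-cores coding per the configured `ppc_mode`).
#' When `ppc_mode = "excluded"` the biopsy term contributes nothing and a
#' missing PPC is tolerated; in either other mode a missing PPC is an
#' error.
#'
#' @param records A `patient_records` table (or a single-row data frame).
#' @param coefs A [coefficient_set()].
#' @param cause `"pc"` (prostate cancer) or `"npc"` (other causes).
#' @return Numeric vector of prognostic indices, one per record.
#' @export
prognostic_index <- function(records, coefs, cause = c("pc", "npc")) {
  cause <- match.arg(cause)
  stopifnot(inherits(coefs, "coefficient_set"))
  if (!inherits(records, "patient_records")) records <- patient_records(records)
  betas <- coefs$betas[[cause]]
  pi <- numeric(nrow(records))
  for (term in names(betas)) {
    x <- .term_value(records, coefs, term)
    if (is.null(x)) next  # ppc term under excluded mode
    pi <- pi + betas[[term]] * x
  }
  pi
}

# Evaluate one transformed covariate term; NULL when the term is inactive.
.term_value <- function(records, coefs, term) {
  tr <- coefs$transforms[[term]]
  if (tr$type == "ppc" && coefs$ppc_mode == "excluded") return(NULL)
  v <- records[[tr$variable]]
  if (is.null(v)) stop("covariate '", tr$variable, "' absent from cohort")
  if (anyNA(v)) {
    stop("missing covariate '", tr$variable, "' for patient(s): ",
         paste(utils::head(records$patient_id[is.na(v)], 5), collapse = ", "))
  }
  center <- if (is.null(tr$center)) 0 else tr$center
  switch(tr$type,
         identity = as.numeric(v) - center,
         log = {
           if (any(as.numeric(v) <= 0)) {
             stop("log transform of non-positive '", tr$variable, "'")
           }
           log(as.numeric(v)) - center
         },
         indicator = as.numeric(v == tr$level),
         ppc = {
           p <- as.numeric(v)
           if (coefs$ppc_mode == "dichotomous_50") as.numeric(p >= 0.5) else p
         })
}

# Annual cause-specific hazard matrix (n x 15) for a scenario.
# scenario: "conservative", "radical", or "as_treated" (per-patient: radical
# HR for prostatectomy/radiotherapy, ADT multiplier for adt, 1 otherwise).
.hazard_matrix <- function(records, coefs, cause, scenario) {
  pi <- prognostic_index(records, coefs, cause)
  lam <- outer(exp(pi), coefs$baseline_hazard[[cause]])
  if (cause == "pc") {
    mult <- switch(scenario,
                   conservative = rep(1, nrow(records)),
                   radical = rep(coefs$radical_hr_pc, nrow(records)),
                   as_treated = {
                     tr <- records$treatment
                     if (anyNA(tr)) {
                       stop("as_treated scenario needs treatment for every ",
                            "patient")
                     }
                     ifelse(tr %in% c("prostatectomy", "radiotherapy"),
                            coefs$radical_hr_pc,
                            ifelse(tr == "adt", coefs$adt_hr_pc, 1))
                   },
                   stop("unknown scenario: ", scenario))
    lam <- lam * mult
  }
  lam
}

# Exact competing-risks decomposition for piecewise-constant annual hazards.
# lam_pc, lam_npc: n x 15 matrices.  Returns list of n x 15 matrices.
.cif_engine <- function(lam_pc, lam_npc) {
  n <- nrow(lam_pc)
  k <- ncol(lam_pc)
  surv <- matrix(0, n, k)
  cif_pc <- matrix(0, n, k)
  cif_npc <- matrix(0, n, k)
  s_prev <- rep(1, n)
  cp <- cn <- rep(0, n)
  for (u in seq_len(k)) {
    lp <- lam_pc[, u]
    ln <- lam_npc[, u]
    tot <- lp + ln
    dead <- s_prev * (1 - exp(-tot))      # mass dying in year u
    frac_p <- ifelse(tot > 0, lp / tot, 0)
    cp <- cp + dead * frac_p
    cn <- cn + dead * (1 - frac_p)
    s_prev <- s_prev * exp(-tot)
    cif_pc[, u] <- cp
    cif_npc[, u] <- cn
    surv[, u] <- s_prev
  }
  list(cif_pc = cif_pc, cif_npc = cif_npc, surv = surv)
}

#' Competing-risks cumulative incidence for one patient
#'
#' With per-year cause-specific hazards
#' \eqn{\lambda_k(u) = h_{0k}(u) e^{PI_k}} (times the radical hazard ratio
#' on the cancer cause where the scenario applies it), overall survival is
#' \eqn{S(t) = \exp(-\sum_{u \le t} (\lambda_{pc}(u)+\lambda_{npc}(u)))}
#' and the cumulative incidence of cause k is
#' \deqn{CIF_k(t) = \sum_{u \le t} S(u-1)
#'       \frac{\lambda_k(u)}{\lambda_{pc}(u)+\lambda_{npc}(u)}
#'       (1 - e^{-(\lambda_{pc}(u)+\lambda_{npc}(u))}),}
#' the exact decomposition for piecewise-constant hazards; a year with both
#' hazards zero contributes nothing.  All-cause mortality is
#' \eqn{ACM(t) = 1 - S(t)} and the conservation identity
#' \eqn{CIF_{pc} + CIF_{npc} + S = 1} holds to machine precision at every
#' grid point.
#'
#' @param record A single-row `patient_records` table.
#' @param coefs A [coefficient_set()].
#' @return An object of class `risk_prediction`: for each scenario
#'   (`as_treated`, `conservative`, `radical`) vectors `cif_pc`, `cif_npc`,
#'   `surv`, `acm` over years 1..15, plus `treatment_benefit(t) =
#'   acm_conservative(t) - acm_radical(t)`.
#' @export
cumulative_incidence <- function(record, coefs) {
  if (!inherits(record, "patient_records")) record <- patient_records(record)
  if (nrow(record) != 1) stop("cumulative_incidence expects a single record")
  preds <- predict_cohort(record, coefs)
  out <- lapply(preds$scenarios, function(s) {
    list(cif_pc = s$cif_pc[1, ], cif_npc = s$cif_npc[1, ],
         surv = s$surv[1, ], acm = 1 - s$surv[1, ])
  })
  out$treatment_benefit <- (1 - out$conservative$surv) -
    (1 - out$radical$surv)
  out$years <- seq_len(HORIZON_YEARS)
  class(out) <- "risk_prediction"
  out
}

#' Predict annual risks for a whole cohort
#'
#' Vectorised competing-risks prediction over years 1..15 for each of the
#' three treatment scenarios.  Under `as_treated`, men who received
#' prostatectomy or radiotherapy are evaluated with the radical hazard
#' ratio on the cancer cause; men on androgen deprivation monotherapy with
#' the configured `adt_hr_pc` multiplier (default 1, i.e. the conservative
#' hazards); conservatively managed men with unmodified hazards.
#'
#' @param cohort A `patient_records` table.
#' @param coefs A [coefficient_set()].
#' @return An object of class `risk_prediction_set`: `patient_id`, `years`,
#'   and `scenarios`, a list keyed by scenario of lists of n x 15 matrices
#'   `cif_pc`, `cif_npc`, `surv`.
#' @export
predict_cohort <- function(cohort, coefs) {
  if (!inherits(cohort, "patient_records")) cohort <- patient_records(cohort)
  stopifnot(inherits(coefs, "coefficient_set"))
  lam_npc <- .hazard_matrix(cohort, coefs, "npc", "conservative")
  scenarios <- list()
  for (sc in c("as_treated", "conservative", "radical")) {
    lam_pc <- .hazard_matrix(cohort, coefs, "pc", sc)
    scenarios[[sc]] <- .cif_engine(lam_pc, lam_npc)
  }
  structure(list(patient_id = cohort$patient_id,
                 years = seq_len(HORIZON_YEARS),
                 scenarios = scenarios),
            class = "risk_prediction_set")
}

# Interpolate an n x 15 annual CIF/risk matrix at per-patient times in
# [0, 15] (linear between grid points, 0 at t = 0).
.interp_annual <- function(mat, times) {
  n <- nrow(mat)
  stopifnot(length(times) == n)
  if (any(times < 0)) stop("negative follow-up time")
  t <- pmin(times, HORIZON_YEARS)
  grid <- cbind(0, mat)             # columns for t = 0..15
  u0 <- pmin(floor(t), HORIZON_YEARS - 1)
  frac <- t - u0
  idx <- cbind(seq_len(n), u0 + 1)
  grid[idx] * (1 - frac) + grid[cbind(seq_len(n), u0 + 2)] * frac
}

#' Expected numbers of deaths given available follow-up
#'
#' Sums each patient's model-predicted cumulative risk evaluated at an
#' evaluation time capped at `horizon_cap` years, interpolating linearly
#' between the annual grid points, under the as-treated scenario:
#' \eqn{E_k = \sum_i CIF_k(\min(t_i, cap))} and
#' \eqn{E_{acm} = \sum_i (1 - S_i(\min(t_i, cap)))}.
#'
#' By default the evaluation time is each patient's *potential* follow-up
#' (diagnosis to the administrative censoring date) when `admin_censor_date`
#' is given and diagnosis dates are available: with administrative
#' censoring the potential time is known for everyone, including the men
#' who died, and the expected count is then an unbiased estimate of the
#' observed count under a correct model.  Without an administrative date
#' the observed follow-up time is used (the conventional
#' "available follow-up" evaluation), which slightly underestimates risk
#' among men who died early.
#'
#' @param cohort A `patient_records` table with `followup_years`.
#' @param coefs A [coefficient_set()].
#' @param horizon_cap Cap on the evaluation time, years in (0, 15].
#' @param admin_censor_date Optional administrative censoring `Date`.
#' @return A list with totals `E_pc`, `E_npc`, `E_acm` and a data frame
#'   `contributions` (per-patient expected risks and the evaluation time
#'   used).
#' @export
expected_events <- function(cohort, coefs, horizon_cap = 15,
                            admin_censor_date = NULL) {
  if (!inherits(cohort, "patient_records")) cohort <- patient_records(cohort)
  stopifnot(horizon_cap > 0, horizon_cap <= HORIZON_YEARS)
  fu <- cohort$followup_years
  if (anyNA(fu)) stop("followup_years required for every patient")
  if (any(fu < 0)) stop("negative follow-up")
  eval_time <- fu
  if (!is.null(admin_censor_date) && !anyNA(cohort$dx_date)) {
    potential <- as.numeric(as.Date(admin_censor_date) - cohort$dx_date) /
      365.25
    # emigration etc. may censor before the administrative date: keep the
    # larger of observed and potential is wrong; the potential time is the
    # administrative horizon, observed censoring earlier than it (while
    # alive) caps the evaluation.
    eval_time <- ifelse(cohort$event == "censored",
                        pmin(fu, potential), potential)
  }
  eval_time <- pmin(eval_time, horizon_cap)
  preds <- predict_cohort(cohort, coefs)
  at <- preds$scenarios$as_treated
  e_pc <- .interp_annual(at$cif_pc, eval_time)
  e_npc <- .interp_annual(at$cif_npc, eval_time)
  e_acm <- .interp_annual(1 - at$surv, eval_time)
  list(E_pc = sum(e_pc), E_npc = sum(e_npc), E_acm = sum(e_acm),
       contributions = data.frame(patient_id = cohort$patient_id,
                                  eval_time = eval_time,
                                  e_pc = e_pc, e_npc = e_npc, e_acm = e_acm,
                                  stringsAsFactors = FALSE))
}
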