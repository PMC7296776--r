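#' Observed-to-expected ratio
#'
#' Mean-calibration summary of an external validation: the raw ratio both
#' ways (`oe` = observed / expected, `eo` = expected / observed) plus the
#' conventional "1:x" label in which the observed count is normalised to 1
#' and `x` is expected / observed to three decimals.
#'
#' @param observed Positive observed event count.
#' @param expected Positive expected (model-predicted) event count.
#' @return A list with `observed`, `expected`, `oe`, `eo`, `label`.
#' @export
oe_ratio <- function(observed, expected) {
  if (!is.finite(expected) || expected <= 0) stop("expected must be > 0")
  if (!is.finite(observed) || observed <= 0) stop("observed must be > 0")
  list(observed = observed, expected = expected,
       oe = observed / expected, eo = expected / observed,
       label = sprintf("1:%.3f", expected / observed))
}

#' Quintile calibration with a grouped chi-square goodness-of-fit test
#'
#' Ranks patients by predicted cumulative risk, cuts them into
#' equal-count groups (ties at cut boundaries broken by stable input
#' order), and compares observed with expected event counts per group.
#' The goodness-of-fit statistic is the grouped
#' \eqn{\chi^2 = \sum_g (O_g - E_g)^2 / E_g} with `df = groups - 1`
#' degrees of freedom (configurable), the grouped-survival variant in the
#' May--Hosmer tradition.
#'
#' @param predicted Per-patient expected cumulative risk (from
#'   [expected_events()] contributions) on the probability scale.
#' @param observed Logical per-patient indicator of the outcome event.
#' @param groups Number of risk groups (default 5 quintiles).
#' @param df Degrees of freedom for the chi-square reference (default
#'   `groups - 1`).
#' @return An object of class `calibration_table`: a data frame with one
#'   row per group (`group`, `n`, `observed`, `expected`, `oe`,
#'   `pct_diff`) and attributes `chisq`, `df`, `p_value`.
#' @export
quintile_calibration <- function(predicted, observed, groups = 5,
                                 df = groups - 1) {
  n <- length(predicted)
  stopifnot(length(observed) == n, groups >= 2)
  if (n < groups) stop("need at least as many patients as groups")
  if (anyNA(predicted) || any(!is.finite(predicted))) {
    stop("predictions must be finite")
  }
  observed <- as.logical(observed)
  ord <- order(predicted)                      # stable: ties keep input order
  grp <- ceiling(seq_len(n) * groups / n)      # equal-count groups
  grp_of <- integer(n)
  grp_of[ord] <- grp
  O <- tapply(observed, grp_of, sum)
  E <- tapply(predicted, grp_of, sum)
  if (any(E == 0)) {
    stop("a risk group has zero expected events; merge groups")
  }
  tab <- data.frame(group = as.integer(names(O)),
                    n = as.integer(table(grp_of)),
                    observed = as.numeric(O), expected = as.numeric(E),
                    oe = as.numeric(O) / as.numeric(E),
                    pct_diff = round(100 * abs(as.numeric(E) -
                                                 as.numeric(O)) /
                                       pmax(as.numeric(O), 1), 1))
  chisq <- sum((tab$observed - tab$expected)^2 / tab$expected)
  structure(tab, chisq = chisq, df = df,
            p_value = pchisq(chisq, df, lower.tail = FALSE),
            class = c("calibration_table", "data.frame"))
}

#' Calibration within cohort subgroups
#'
#' Observed and expected deaths per subgroup and outcome (prostate
#' cancer, other cause, any cause), with a percent difference.  The
#' percent-difference convention is configurable and always reported
#' alongside the numbers: `"obs"` (default) is `100 |E - O| / O`, `"exp"`
#' divides by E, `"n"` by the subgroup size.
#'
#' @param cohort A filtered `patient_records` table.
#' @param coefs A [coefficient_set()].
#' @param grouping Either the name of a grouping rule
#'   (`"treatment_group"` for conservative/radical/adt,
#'   `"conservative_subtype"`, `"treatment"`) or a factor/character vector
#'   with one value per patient.
#' @param convention Percent-difference convention, see above.
#' @param horizon_cap Evaluation-time cap in years, default 15.
#' @param admin_censor_date Optional administrative censoring date passed
#'   to [expected_events()].
#' @return A `calibration_table` data frame with one row per subgroup and
#'   outcome (`group`, `outcome`, `n`, `observed`, `expected`, `oe`,
#'   `pct_diff`); attribute `convention` records the formula used.
#' @export
subgroup_calibration <- function(cohort, coefs,
                                 grouping = "treatment_group",
                                 convention = c("obs", "exp", "n"),
                                 horizon_cap = 15,
                                 admin_censor_date = NULL) {
  convention <- match.arg(convention)
  if (!inherits(cohort, "patient_records")) cohort <- patient_records(cohort)
  if (is.character(grouping) && length(grouping) == 1) {
    grouping <- switch(grouping,
                       treatment_group = unname(
                         assign_treatment_groups(cohort)),
                       conservative_subtype = cohort$conservative_subtype,
                       treatment = cohort$treatment,
                       stop("unknown grouping rule: ", grouping))
  }
  stopifnot(length(grouping) == nrow(cohort))
  ee <- expected_events(cohort, coefs, horizon_cap = horizon_cap,
                        admin_censor_date = admin_censor_date)
  contrib <- ee$contributions
  in_window <- cohort$followup_years <= horizon_cap
  obs <- data.frame(
    pc = cohort$event == "pca_death" & in_window,
    npc = cohort$event == "other_death" & in_window,
    acm = cohort$event != "censored" & in_window)
  rows <- list()
  for (g in unique(grouping[!is.na(grouping)])) {
    mask <- !is.na(grouping) & grouping == g
    if (!any(mask)) {
      warning("empty subgroup skipped: ", g)
      next
    }
    for (outc in c("pc", "npc", "acm")) {
      O <- sum(obs[[outc]][mask])
      E <- sum(contrib[[paste0("e_", outc)]][mask])
      base <- switch(convention, obs = O, exp = E, n = sum(mask))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, outcome = outc, n = sum(mask),
        observed = O, expected = E,
        oe = if (E > 0) O / E else NA_real_,
        pct_diff = if (base > 0) round(100 * abs(E - O) / base, 1)
        else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, convention = convention,
            class = c("calibration_table", "data.frame"))
}
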