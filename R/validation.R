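#' Run the full discrimination / calibration validation
#'
#' Assembles, for a filtered cohort and a coefficient configuration, the
#' complete external-validation report:
#' \itemize{
#'   \item Harrell's c (with jackknife SE and 95% CI) for 15-year
#'     prostate-cancer-specific mortality (PCSM) and all-cause mortality
#'     (ACM), overall and within the conservative, radical and ADT
#'     treatment groups (plus the active-surveillance subgroup when
#'     annotated).  The model's score is its predicted 15-year cumulative
#'     risk under the as-treated scenario.
#'   \item The same c-indices for each requested comparator system
#'     (ordinal labels used directly as scores) with paired jackknife
#'     p-values against the model.
#'   \item Overall observed-to-expected counts per outcome, quintile
#'     calibration tables with the grouped chi-square goodness-of-fit
#'     test, and subgroup calibration by treatment group and conservative
#'     subtype.
#' }
#'
#' @param cohort A filtered `patient_records` table with follow-up and
#'   events.
#' @param coefs A [coefficient_set()].
#' @param comparators Character vector among `"capra"`, `"eau"`, `"nccn"`.
#' @param quintiles Number of calibration risk groups (default 5).
#' @param horizon_cap Evaluation-time cap, years (default 15).
#' @param admin_censor_date Optional administrative censoring date used to
#'   evaluate expected events at potential follow-up.
#' @param include_as_subgroup Also report the active-surveillance subgroup
#'   when conservative subtypes are annotated.
#' @param pct_convention Percent-difference convention for subgroup
#'   calibration.
#' @return An object of class `validation_report`.
#' @export
run_validation <- function(cohort, coefs,
                           comparators = c("capra", "eau", "nccn"),
                           quintiles = 5, horizon_cap = 15,
                           admin_censor_date = NULL,
                           include_as_subgroup = TRUE,
                           pct_convention = "obs") {
  if (!inherits(cohort, "patient_records")) cohort <- patient_records(cohort)
  comparators <- match.arg(comparators, c("capra", "eau", "nccn"),
                           several.ok = TRUE)
  groups <- assign_treatment_groups(cohort)
  preds <- predict_cohort(cohort, coefs)
  at <- preds$scenarios$as_treated
  score_pc <- at$cif_pc[, HORIZON_YEARS]
  score_acm <- 1 - at$surv[, HORIZON_YEARS]
  fu <- cohort$followup_years
  ev_pc <- cohort$event == "pca_death"
  ev_acm <- cohort$event != "censored"

  comp_scores <- lapply(setNames(comparators, comparators), function(s) {
    classify_cohort(cohort, s)$value
  })

  subsets <- list(overall = rep(TRUE, nrow(cohort)),
                  conservative = unname(groups) == "conservative",
                  radical = unname(groups) == "radical",
                  adt = unname(groups) == "adt")
  if (include_as_subgroup && any(!is.na(cohort$conservative_subtype) &
                                 cohort$conservative_subtype ==
                                 "active_surveillance")) {
    subsets$active_surveillance <-
      !is.na(cohort$conservative_subtype) &
      cohort$conservative_subtype == "active_surveillance"
  }

  discrimination <- list()
  for (grp in names(subsets)) {
    mask <- subsets[[grp]]
    if (sum(mask) < 2) next
    for (outc in c("pcsm", "acm")) {
      sc <- if (outc == "pcsm") score_pc else score_acm
      ev <- if (outc == "pcsm") ev_pc else ev_acm
      model_c <- tryCatch(harrell_c(sc[mask], fu[mask], ev[mask]),
                          error = function(e) NULL)
      if (is.null(model_c)) next
      row <- list(group = grp, outcome = outc, tool = "model",
                  n = sum(mask), c = model_c$c, se = model_c$se,
                  ci_lo = model_c$ci95[1], ci_hi = model_c$ci95[2],
                  p_vs_model = NA_real_)
      discrimination[[length(discrimination) + 1]] <- row
      for (cs in names(comp_scores)) {
        cmp <- tryCatch(compare_c(sc[mask], comp_scores[[cs]][mask],
                                  fu[mask], ev[mask]),
                        error = function(e) NULL)
        if (is.null(cmp)) next
        discrimination[[length(discrimination) + 1]] <-
          list(group = grp, outcome = outc, tool = cs, n = sum(mask),
               c = cmp$b$c, se = cmp$b$se,
               ci_lo = cmp$b$ci95[1], ci_hi = cmp$b$ci95[2],
               p_vs_model = cmp$p)
      }
    }
  }
  discrimination <- do.call(rbind, lapply(discrimination, as.data.frame))

  ee <- expected_events(cohort, coefs, horizon_cap = horizon_cap,
                        admin_censor_date = admin_censor_date)
  in_window <- fu <= horizon_cap
  observed <- c(pc = sum(ev_pc & in_window),
                npc = sum(cohort$event == "other_death" & in_window),
                acm = sum(ev_acm & in_window))
  expected <- c(pc = ee$E_pc, npc = ee$E_npc, acm = ee$E_acm)
  overall_oe <- lapply(setNames(names(observed), names(observed)),
                       function(k) oe_ratio(observed[[k]], expected[[k]]))

  quintile_tables <- lapply(
    setNames(c("pc", "npc", "acm"), c("pc", "npc", "acm")),
    function(outc) {
      obs_vec <- switch(outc, pc = ev_pc & in_window,
                        npc = cohort$event == "other_death" & in_window,
                        acm = ev_acm & in_window)
      quintile_calibration(ee$contributions[[paste0("e_", outc)]],
                           obs_vec, groups = quintiles)
    })

  subgroup_tables <- list(
    treatment = subgroup_calibration(cohort, coefs,
                                     grouping = "treatment",
                                     convention = pct_convention,
                                     horizon_cap = horizon_cap,
                                     admin_censor_date = admin_censor_date))
  if (any(!is.na(cohort$conservative_subtype))) {
    subgroup_tables$conservative_subtype <-
      subgroup_calibration(cohort, coefs,
                           grouping = "conservative_subtype",
                           convention = pct_convention,
                           horizon_cap = horizon_cap,
                           admin_censor_date = admin_censor_date)
  }

  structure(list(
    n = nrow(cohort),
    summary = summarize_cohort(cohort),
    discrimination = discrimination,
    overall_observed = observed,
    overall_expected = expected,
    overall_oe = overall_oe,
    quintile_calibration = quintile_tables,
    subgroup_calibration = subgroup_tables,
    options = list(comparators = comparators, quintiles = quintiles,
                   horizon_cap = horizon_cap,
                   admin_censor_date = if (is.null(admin_censor_date))
                     NA_character_ else as.character(admin_censor_date),
                   pct_convention = pct_convention)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %d patients\n", x$n))
  ov <- x$discrimination[x$discrimination$group == "overall" &
                           x$discrimination$tool == "model", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  c-index (%s): %.3f (SE %.4f)\n",
                toupper(ov$outcome[i]), ov$c[i], ov$se[i]))
  }
  cat(sprintf("  Overall O:E (any cause): %s (O = %d, E = %.1f)\n",
              x$overall_oe$acm$label, x$overall_observed[["acm"]],
              x$overall_expected[["acm"]]))
  gof <- attr(x$quintile_calibration$acm, "p_value")
  cat(sprintf("  Quintile GOF (any cause): chi-square %.2f, p = %.3f\n",
              attr(x$quintile_calibration$acm, "chisq"), gof))
  invisible(x)
}
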