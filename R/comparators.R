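#' Bundled comparator configurations
#'
#' The comparator systems ship as versioned configuration objects rather
#' than hard-coded rules: the validation paper-trail for such systems
#' lives in their own guideline sources, and editions differ.  Two
#' registry-driven imputations are wired in as defaults everywhere:
#' clinical stage T2 without sub-stage is scored as T2a, and a missing
#' proportion of positive cores falls in the "< 34%" band of the CAPRA
#' score.
#'
#' `capra_schedule()` returns the UCSF CAPRA point schedule: age (< 50: 0,
#' >= 50: 1), PSA bands (<= 6: 0, (6, 10]: 1, (10, 20]: 2, (20, 30]: 3,
#' > 30: 4), Gleason-pattern points derived from grade group via the map
#' GG1 -> (3, 3), GG2 -> (3, 4), GG3 -> (4, 3), GG4 -> (4, 4),
#' GG5 -> (4, 5) (no pattern 4/5: 0; secondary 4/5: 1; primary 4/5: 3),
#' T stage (T1/T2: 0, T3/T4: 1 -- stages above T3a map to the highest
#' band), and PPC (< 34%: 0, >= 34%: 1).  Total range 0--10.
#'
#' @return A configuration list.
#' @export
capra_schedule <- function() {
  list(
    version = "capra-2005-bundled",
    age_cut = 50, age_points = c(0, 1),
    psa_breaks = c(-Inf, 6, 10, 20, 30, Inf), psa_points = 0:4,
    # grade group -> (primary, secondary) Gleason pattern -> points
    gleason_points = c(0, 1, 3, 3, 3),
    t_points = c(T1 = 0, T2 = 0, T3 = 1, T4 = 1),
    ppc_cut = 0.34, ppc_points = c(0, 1)
  )
}

#' @rdname capra_schedule
#' @export
eau_definition <- function() {
  list(version = "eau-3-stratum-bundled",
       low = list(psa_lt = 10, gg_max = 1, stage_max = "T2"),
       high = list(psa_gt = 20, gg_min = 4, stage_min = "T3"))
}

#' @rdname capra_schedule
#' @export
nccn_definition <- function() {
  # NCCN-style approximation over the available variables: the very-low
  # stratum (needing core counts and PSA density) is collapsed into low,
  # documented as a configurable approximation.
  list(version = "nccn-style-bundled",
       strata = c("low", "intermediate", "high", "very_high"),
       intermediate = list(psa_ge = 10, psa_le = 20, gg = c(2, 3)),
       high = list(psa_gt = 20, gg = 4, stage = c("T3")),
       very_high = list(gg = 5, stage = c("T4")))
}

.check_classifier_inputs <- function(records, need_age = FALSE) {
  if (!inherits(records, "patient_records")) {
    records <- patient_records(records)
  }
  if (anyNA(records$psa) || any(records$psa <= 0)) {
    stop("classifier requires positive PSA for every patient")
  }
  if (anyNA(records$grade_group)) stop("classifier requires grade_group")
  if (anyNA(records$t_stage)) stop("classifier requires t_stage")
  if (need_age && anyNA(records$age_dx)) stop("classifier requires age_dx")
  records
}

.risk_labels <- function(records, system, value, label) {
  data.frame(patient_id = records$patient_id, system = system,
             value = as.integer(value), label = label,
             stringsAsFactors = FALSE)
}

#' UCSF CAPRA score
#'
#' Sums points over age, PSA band, Gleason-pattern category (derived from
#' the grade group), clinical T stage and the proportion-of-positive-cores
#' band.  Missing PPC scores as the "< 34%" band; T2 without sub-stage
#' scores as T2a (both registry imputations).  Deterministic and total on
#' filtered cohorts.
#'
#' @param records A `patient_records` table.
#' @param schedule Point schedule, see [capra_schedule()].
#' @return A data frame with `patient_id`, `system`, ordinal `value`
#'   (points, 0--10) and `label`.
#' @export
capra_score <- function(records, schedule = capra_schedule()) {
  records <- .check_classifier_inputs(records, need_age = TRUE)
  pts_age <- schedule$age_points[1 + (records$age_dx >= schedule$age_cut)]
  pts_psa <- schedule$psa_points[
    cut(records$psa, schedule$psa_breaks, labels = FALSE)]
  pts_gl <- schedule$gleason_points[records$grade_group]
  pts_t <- schedule$t_points[records$t_stage]
  ppc <- records$ppc
  high_ppc <- !is.na(ppc) & ppc >= schedule$ppc_cut
  pts_ppc <- schedule$ppc_points[1 + high_ppc]
  total <- pts_age + pts_psa + pts_gl + pts_t + pts_ppc
  .risk_labels(records, "capra", total, sprintf("capra_%d", total))
}

#' EAU 3-stratum risk group
#'
#' Low risk: PSA < 10 ng/ml and grade group 1 and stage at most
#' T2a-equivalent (T2 without sub-stage is treated as T2a); high risk:
#' PSA > 20 ng/ml or grade group >= 4 or stage >= T3; otherwise
#' intermediate.  Ordinal coding 0 = low, 1 = intermediate, 2 = high.
#'
#' @param records A `patient_records` table.
#' @param definition See [eau_definition()].
#' @return A data frame as in [capra_score()].
#' @export
eau_risk_group <- function(records, definition = eau_definition()) {
  records <- .check_classifier_inputs(records)
  stage_num <- match(records$t_stage, T_STAGE_LEVELS)
  high <- records$psa > definition$high$psa_gt |
    records$grade_group >= definition$high$gg_min |
    stage_num >= match(definition$high$stage_min, T_STAGE_LEVELS)
  low <- !high & records$psa < definition$low$psa_lt &
    records$grade_group <= definition$low$gg_max &
    stage_num <= match(definition$low$stage_max, T_STAGE_LEVELS)
  value <- ifelse(high, 2L, ifelse(low, 0L, 1L))
  .risk_labels(records, "eau",
               value, c("low", "intermediate", "high")[value + 1L])
}

#' NCCN-style risk stratum
#'
#' Ordinal label over four strata (low / intermediate / high / very high)
#' from PSA, grade group and clinical stage; a documented approximation of
#' the NCCN table over the variables a registry records (very-low risk,
#' which needs core counts and PSA density, is collapsed into low).
#' Coding 0 = low .. 3 = very high.
#'
#' @param records A `patient_records` table.
#' @param definition See [nccn_definition()].
#' @return A data frame as in [capra_score()].
#' @export
nccn_risk_group <- function(records, definition = nccn_definition()) {
  records <- .check_classifier_inputs(records)
  gg <- records$grade_group
  psa <- records$psa
  st <- records$t_stage
  very_high <- gg >= 5 | st == "T4"
  high <- !very_high & (psa > definition$high$psa_gt | gg == 4 | st == "T3")
  intermediate <- !very_high & !high &
    (gg %in% definition$intermediate$gg |
       (psa >= definition$intermediate$psa_ge &
          psa <= definition$intermediate$psa_le))
  value <- ifelse(very_high, 3L, ifelse(high, 2L,
                                        ifelse(intermediate, 1L, 0L)))
  .risk_labels(records, "nccn", value, definition$strata[value + 1L])
}

#' Classify a cohort under one comparator system
#'
#' @param records A `patient_records` table.
#' @param system `"capra"`, `"eau"` or `"nccn"`.
#' @param config Optional system configuration overriding the bundled one.
#' @return A data frame of per-patient labels.
#' @export
classify_cohort <- function(records, system = c("capra", "eau", "nccn"),
                            config = NULL) {
  system <- match.arg(system)
  switch(system,
         capra = capra_score(records,
                             if (is.null(config)) capra_schedule() else config),
         eau = eau_risk_group(records,
                              if (is.null(config)) eau_definition() else config),
         nccn = nccn_risk_group(records,
                                if (is.null(config)) nccn_definition()
                                else config))
}
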