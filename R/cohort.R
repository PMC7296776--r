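#' Construct a patient-record table
#'
#' Coerces a data frame to the canonical cohort layout: one row per diagnosed
#' man, with the covariates used by the prognostic model, primary treatment,
#' comorbidity flag, follow-up and event type.  Missing values are permitted
#' (pre-filter data routinely lack grade group, PSA or treatment); hard
#' invariants (non-negative follow-up, PPC within \[0, 1\], known category
#' codes) are enforced on the non-missing values.
#'
#' Canonical columns: `patient_id`, `age_dx` (years), `psa` (ng/ml),
#' `t_stage` (`T1`--`T4`, no sub-stage), `grade_group` (ISUP 1--5), `ppc`
#' (proportion of positive biopsy cores, fraction), `treatment`
#' (`conservative`, `prostatectomy`, `radiotherapy`, `adt`),
#' `conservative_subtype` (optional annotation for conservatively managed
#' men), `comorbid` (logical: Charlson >= 1 plus recent admission),
#' `metastatic` (logical), `dx_date` (ISO date, optional when
#' `followup_years` is supplied directly), `followup_years`, `event`
#' (`pca_death`, `other_death`, `censored`).
#'
#' @param df A data frame containing at least `patient_id`; other canonical
#'   columns are added as `NA` when absent.
#' @return A data frame of class `patient_records`.
#' @export
patient_records <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"patient_id" %in% names(df)) {
    stop("cohort table must contain a 'patient_id' column")
  }
  extra <- setdiff(names(df), COHORT_COLUMNS)
  if (length(extra) > 0) {
    stop("unknown cohort column(s): ", paste(extra, collapse = ", "),
         "; expected a subset of: ", paste(COHORT_COLUMNS, collapse = ", "))
  }
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$patient_id)) {
    stop("duplicate patient_id values in cohort table")
  }
  n <- nrow(out)
  get_col <- function(name, default = NA) {
    if (name %in% names(df)) df[[name]] else rep(default, n)
  }
  out$age_dx <- as.numeric(get_col("age_dx"))
  out$psa <- as.numeric(get_col("psa"))
  out$t_stage <- .coerce_enum(get_col("t_stage"), T_STAGE_LEVELS, "t_stage",
                              out$patient_id)
  out$grade_group <- .coerce_grade(get_col("grade_group"), out$patient_id)
  out$ppc <- as.numeric(get_col("ppc"))
  out$treatment <- .coerce_enum(get_col("treatment"), TREATMENT_LEVELS,
                                "treatment", out$patient_id)
  out$conservative_subtype <- .coerce_enum(get_col("conservative_subtype"),
                                           CONSERVATIVE_SUBTYPES,
                                           "conservative_subtype",
                                           out$patient_id)
  out$comorbid <- .coerce_logical(get_col("comorbid"))
  out$metastatic <- .coerce_logical(get_col("metastatic"))
  dx <- get_col("dx_date")
  out$dx_date <- if (inherits(dx, "Date")) dx else as.Date(as.character(dx))
  out$followup_years <- as.numeric(get_col("followup_years"))
  out$event <- .coerce_enum(get_col("event"), EVENT_LEVELS, "event",
                            out$patient_id)

  bad_fu <- !is.na(out$followup_years) & out$followup_years < 0
  if (any(bad_fu)) {
    stop("negative followup_years for patient(s): ",
         paste(utils::head(out$patient_id[bad_fu], 5), collapse = ", "))
  }
  bad_ppc <- !is.na(out$ppc) & (out$ppc < 0 | out$ppc > 1)
  if (any(bad_ppc)) {
    stop("ppc outside [0, 1] for patient(s): ",
         paste(utils::head(out$patient_id[bad_ppc], 5), collapse = ", "))
  }
  bad_sub <- !is.na(out$conservative_subtype) &
    (is.na(out$treatment) | out$treatment != "conservative")
  if (any(bad_sub)) {
    stop("conservative_subtype set for non-conservative patient(s): ",
         paste(utils::head(out$patient_id[bad_sub], 5), collapse = ", "))
  }
  class(out) <- c("patient_records", "data.frame")
  out
}

.coerce_enum <- function(x, levels, name, ids) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop("invalid ", name, " value(s) ",
         paste(unique(x[bad]), collapse = ", "),
         " for patient(s): ", paste(utils::head(ids[bad], 5), collapse = ", "),
         " (expected one of: ", paste(levels, collapse = ", "), ")")
  }
  x
}

.coerce_grade <- function(x, ids) {
  g <- suppressWarnings(as.integer(x))
  bad <- !is.na(g) & (g < 1L | g > 5L)
  if (any(bad)) {
    stop("grade_group outside 1-5 for patient(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  g
}

.coerce_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  x[x == ""] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("invalid logical value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Inclusion criteria for cohort assembly
#'
#' Registry-style inclusion rules: a diagnostic calendar window (inclusive of
#' both endpoints), a strict PSA upper limit, exclusion of metastatic
#' disease, and completeness of the variables mandatory for the model.
#'
#' @param dx_window Length-2 `Date` vector (start, end) of the diagnosis
#'   window.  Default 2000-01-01 to 2010-12-31.
#' @param psa_max Strict PSA upper bound in ng/ml (records with
#'   `psa >= psa_max` are excluded).  Default 100.
#' @param require_nonmetastatic Exclude men with metastatic disease.
#' @param mandatory_fields Character vector of fields that must be
#'   non-missing.  Default: the six model-mandatory variables (age, PSA,
#'   T stage, grade group, primary treatment, comorbidity).
#' @param missing_m_as_m0 Treat a missing metastatic flag as non-metastatic
#'   (`TRUE`) or exclude such records (`FALSE`, default).  Either way the
#'   decision is logged.
#' @return An object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(dx_window = as.Date(c("2000-01-01",
                                                     "2010-12-31")),
                               psa_max = 100,
                               require_nonmetastatic = TRUE,
                               mandatory_fields = c("age_dx", "psa",
                                                    "t_stage", "grade_group",
                                                    "treatment", "comorbid"),
                               missing_m_as_m0 = FALSE) {
  dx_window <- as.Date(dx_window)
  stopifnot(length(dx_window) == 2, !anyNA(dx_window),
            dx_window[1] < dx_window[2], psa_max > 0)
  bad <- setdiff(mandatory_fields, COHORT_COLUMNS)
  if (length(bad) > 0) stop("unknown mandatory field(s): ",
                            paste(bad, collapse = ", "))
  structure(list(dx_window = dx_window, psa_max = psa_max,
                 require_nonmetastatic = isTRUE(require_nonmetastatic),
                 mandatory_fields = mandatory_fields,
                 missing_m_as_m0 = isTRUE(missing_m_as_m0)),
            class = "inclusion_criteria")
}

#' Apply inclusion and completeness filters to a pre-filter record table
#'
#' Retains records inside the diagnostic window, below the PSA limit,
#' without metastatic disease, and with all mandatory model variables
#' present.  A record failing several rules is counted once in the overall
#' exclusion total; per-reason and per-field tallies are reported
#' separately, so per-field counts may sum to more than the number of
#' excluded records.
#'
#' @param records A `patient_records` table (or coercible data frame),
#'   possibly containing missing fields.
#' @param criteria An [inclusion_criteria()] object.
#' @return A list with components `cohort` (the retained
#'   `patient_records`) and `log`, a list holding `n_input`, `n_retained`,
#'   `n_excluded`, `excluded_pct` (one decimal), `reasons` (named counts of
#'   records failing each rule), `missing_fields` (per-field missingness
#'   tallies among excluded records), and `excluded_ids`.
#' @export
apply_inclusion_filters <- function(records, criteria = inclusion_criteria()) {
  if (!inherits(records, "patient_records")) records <- patient_records(records)
  stopifnot(inherits(criteria, "inclusion_criteria"))
  n <- nrow(records)
  if (n == 0) {
    return(list(cohort = records,
                log = list(n_input = 0L, n_retained = 0L, n_excluded = 0L,
                           excluded_pct = 0, reasons = integer(0),
                           missing_fields = integer(0),
                           excluded_ids = character(0),
                           missing_m_as_m0 = criteria$missing_m_as_m0)))
  }

  fail <- list()
  # Window check only applies when a diagnosis date is recorded; follow-up
  # may be supplied directly, in which case dx_date is optional.
  has_dx <- !is.na(records$dx_date)
  fail$outside_dx_window <- has_dx &
    (records$dx_date < criteria$dx_window[1] |
       records$dx_date > criteria$dx_window[2])
  fail$psa_out_of_range <- !is.na(records$psa) &
    records$psa >= criteria$psa_max
  if (criteria$require_nonmetastatic) {
    m <- records$metastatic
    fail$metastatic <- if (criteria$missing_m_as_m0) {
      !is.na(m) & m
    } else {
      is.na(m) | m
    }
  }
  miss <- vapply(criteria$mandatory_fields,
                 function(f) is.na(records[[f]]), logical(n))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = n)
  fail$missing_mandatory <- rowSums(miss) > 0
  # Records with nonsense follow-up information are rejected, never
  # silently dropped: they surface with their ids in the log.
  fail$invalid_followup <- (!is.na(records$followup_years) &
                              records$followup_years < 0) |
    (!is.na(records$psa) & records$psa <= 0)

  fail_mat <- do.call(cbind, fail)
  excluded <- rowSums(fail_mat) > 0
  keep <- !excluded

  missing_fields <- colSums(miss[excluded, , drop = FALSE])
  names(missing_fields) <- criteria$mandatory_fields

  log <- list(
    n_input = n,
    n_retained = sum(keep),
    n_excluded = sum(excluded),
    excluded_pct = round(100 * sum(excluded) / n, 1),
    reasons = colSums(fail_mat),
    missing_fields = missing_fields,
    excluded_ids = records$patient_id[excluded],
    missing_m_as_m0 = criteria$missing_m_as_m0
  )
  cohort <- records[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  class(cohort) <- c("patient_records", "data.frame")
  list(cohort = cohort, log = log)
}

#' Assign analysis treatment groups
#'
#' Collapses the four primary-treatment codes into the three analysis
#' groups: `conservative`, `radical` (prostatectomy or radiotherapy within
#' 12 months of diagnosis) and `adt` (androgen deprivation monotherapy).
#' The groups partition the cohort.
#'
#' @param cohort A filtered `patient_records` table with no missing
#'   treatment.
#' @return A named character vector mapping `patient_id` to analysis group.
#' @export
assign_treatment_groups <- function(cohort) {
  tr <- cohort$treatment
  if (anyNA(tr)) {
    stop("missing treatment for patient(s): ",
         paste(utils::head(cohort$patient_id[is.na(tr)], 5), collapse = ", "))
  }
  bad <- !(tr %in% TREATMENT_LEVELS)
  if (any(bad)) {
    stop("unknown treatment code(s): ", paste(unique(tr[bad]), collapse = ", "))
  }
  grp <- ifelse(tr %in% c("prostatectomy", "radiotherapy"), "radical", tr)
  setNames(grp, cohort$patient_id)
}

#' Summarise a filtered cohort (baseline table analogue)
#'
#' Computes person-years, median follow-up, event counts (overall and
#' within 10 years of diagnosis), categorical covariate distributions, and
#' crude mortality rates.  Although registry baseline tables often label
#' crude rates "per patient year", values of the order of 1--5 only arise
#' per 100 person-years, and that is the scale used here: rate =
#' events / person-years x 100, reported to two decimals (raw values are
#' retained in `rates_raw`).
#'
#' @param cohort A filtered `patient_records` table with `followup_years`
#'   and `event` present for every row.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  if (!inherits(cohort, "patient_records")) cohort <- patient_records(cohort)
  n <- nrow(cohort)
  if (n == 0) stop("cannot summarise an empty cohort")
  if (anyNA(cohort$followup_years) || anyNA(cohort$event)) {
    stop("followup_years and event must be present for every patient")
  }
  py <- sum(cohort$followup_years)
  if (py <= 0) stop("zero person-years with non-zero cohort size")

  count_events <- function(mask) {
    ev <- cohort$event[mask]
    c(pca_death = sum(ev == "pca_death"),
      other_death = sum(ev == "other_death"),
      any_death = sum(ev != "censored"),
      censored = sum(ev == "censored"))
  }
  events_overall <- count_events(rep(TRUE, n))
  events_10y <- count_events(cohort$followup_years <= 10)

  cat_dist <- function(x, levels) {
    counts <- table(factor(x, levels = levels), useNA = "no")
    data.frame(level = names(counts), n = as.integer(counts),
               pct = round(100 * as.integer(counts) / sum(counts), 1),
               stringsAsFactors = FALSE)
  }
  distributions <- list(
    grade_group = cat_dist(cohort$grade_group, 1:5),
    t_stage = cat_dist(cohort$t_stage, T_STAGE_LEVELS),
    treatment = cat_dist(cohort$treatment, TREATMENT_LEVELS),
    comorbid = cat_dist(ifelse(cohort$comorbid, "comorbid", "none"),
                        c("none", "comorbid"))
  )
  rates_raw <- c(pcsm = 100 * events_overall[["pca_death"]] / py,
                 acm = 100 * events_overall[["any_death"]] / py)
  structure(list(
    n = n,
    person_years = py,
    median_followup = median(cohort$followup_years),
    events = events_overall,
    events_10y = events_10y,
    distributions = distributions,
    age_mean = mean(cohort$age_dx),
    age_sd = stats::sd(cohort$age_dx),
    psa_mean = mean(cohort$psa),
    psa_sd = stats::sd(cohort$psa),
    crude_pcsm_rate = round(rates_raw[["pcsm"]], 2),
    crude_acm_rate = round(rates_raw[["acm"]], 2),
    rates_raw = rates_raw
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d men, %.0f person-years, median follow-up %.1f y\n",
              x$n, x$person_years, x$median_followup))
  cat(sprintf("Deaths: %d prostate cancer, %d other cause, %d censored\n",
              x$events[["pca_death"]], x$events[["other_death"]],
              x$events[["censored"]]))
  cat(sprintf("Crude rates per 100 person-years: PCSM %.2f, ACM %.2f\n",
              x$crude_pcsm_rate, x$crude_acm_rate))
  invisible(x)
}
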