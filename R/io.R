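#' Read and write cohort CSV files
#'
#' The cohort CSV has one row per patient with the canonical columns (see
#' [patient_records()] for the data dictionary); missing values are
#' encoded as empty strings and `dx_date` is ISO-8601.  Reading is strict:
#' unknown columns and invalid enum values are errors addressed by column
#' or row, never silently dropped, and write-then-read round-trips a
#' cohort field-for-field.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv` returns a `patient_records` table;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(names(df) %in% COHORT_COLUMNS)) {
    stop("unknown column(s): ",
         paste(setdiff(names(df), COHORT_COLUMNS), collapse = ", "),
         "; expected schema: ", paste(COHORT_COLUMNS, collapse = ", "))
  }
  for (nm in names(df)) df[[nm]][df[[nm]] == ""] <- NA
  # row-addressed enum validation before full coercion
  for (spec in list(list(col = "event", levels = EVENT_LEVELS),
                    list(col = "treatment", levels = TREATMENT_LEVELS),
                    list(col = "t_stage", levels = T_STAGE_LEVELS))) {
    if (spec$col %in% names(df)) {
      bad <- which(!is.na(df[[spec$col]]) &
                     !(df[[spec$col]] %in% spec$levels))
      if (length(bad) > 0) {
        stop("invalid ", spec$col, " value '", df[[spec$col]][bad[1]],
             "' at row ", bad[1],
             " (expected one of: ", paste(spec$levels, collapse = ", "), ")")
      }
    }
  }
  patient_records(df)
}

#' @rdname read_cohort_csv
#' @param cohort A `patient_records` table.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (!inherits(cohort, "patient_records")) cohort <- patient_records(cohort)
  out <- as.data.frame(cohort)
  out$dx_date <- ifelse(is.na(out$dx_date), NA,
                        format(out$dx_date, "%Y-%m-%d"))
  out$comorbid <- ifelse(is.na(out$comorbid), NA,
                         ifelse(out$comorbid, "true", "false"))
  out$metastatic <- ifelse(is.na(out$metastatic), NA,
                           ifelse(out$metastatic, "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Convert report components to plain lists for JSON serialisation.
.report_to_list <- function(report) {
  cal_tab <- function(tab) {
    out <- list(rows = as.data.frame(tab))
    for (a in c("chisq", "df", "p_value", "convention")) {
      if (!is.null(attr(tab, a))) out[[a]] <- attr(tab, a)
    }
    out
  }
  list(
    n = report$n,
    summary = unclass(report$summary),
    discrimination = report$discrimination,
    overall_observed = as.list(report$overall_observed),
    overall_expected = as.list(report$overall_expected),
    overall_oe = report$overall_oe,
    quintile_calibration = lapply(report$quintile_calibration, cal_tab),
    subgroup_calibration = lapply(report$subgroup_calibration, cal_tab),
    options = report$options
  )
}

#' Write a validation report and its table renderings
#'
#' The JSON report is the single source of truth; the CSV tables are pure
#' views of it: a discrimination table (c-indices and paired p-values per
#' group and tool), a subgroup calibration table (observed, expected and
#' percent difference per treatment group and outcome), and a
#' calibration-curve table (per-quintile observed and expected
#' probabilities per outcome).
#'
#' @param report A `validation_report`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(.report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  files <- c(files, json_path)

  disc_path <- file.path(dir, "discrimination.csv")
  utils::write.csv(report$discrimination, disc_path, row.names = FALSE)
  files <- c(files, disc_path)

  sub <- do.call(rbind, lapply(names(report$subgroup_calibration),
                               function(k) {
                                 tab <- as.data.frame(
                                   report$subgroup_calibration[[k]])
                                 tab$grouping <- k
                                 tab
                               }))
  sub_path <- file.path(dir, "subgroup_calibration.csv")
  utils::write.csv(sub, sub_path, row.names = FALSE)
  files <- c(files, sub_path)

  curves <- do.call(rbind, lapply(names(report$quintile_calibration),
                                  function(k) {
                                    tab <- as.data.frame(
                                      report$quintile_calibration[[k]])
                                    tab$outcome <- k
                                    tab$obs_prob <- tab$observed / tab$n
                                    tab$exp_prob <- tab$expected / tab$n
                                    tab
                                  }))
  curve_path <- file.path(dir, "calibration_curve.csv")
  utils::write.csv(curves, curve_path, row.names = FALSE)
  files <- c(files, curve_path)
  invisible(files)
}
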