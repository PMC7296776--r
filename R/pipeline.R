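#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: input paths (or a request to
#' simulate), the seed, inclusion criteria, calibration settings and the
#' design-decision flags, so that the run log suffices to reproduce a run
#' bit-identically.
#'
#' @param cohort_path Path to a cohort CSV, or `NULL` to simulate.
#' @param coefficients_path Path to a coefficient JSON, or `NULL` for the
#'   bundled illustrative set.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_simulate Cohort size when simulating.
#' @param criteria An [inclusion_criteria()] object.
#' @param comparators Comparator systems to evaluate.
#' @param horizon_cap Evaluation-time cap, years in (0, 15].
#' @param quintiles Number of calibration risk groups (>= 2).
#' @param pct_convention Percent-difference convention.
#' @param admin_censor_date Administrative censoring date or `NULL`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, coefficients_path = NULL,
                            out_dir = "pcrisk-output", seed = 1,
                            n_simulate = 20000,
                            criteria = inclusion_criteria(),
                            comparators = c("capra", "eau", "nccn"),
                            horizon_cap = 15, quintiles = 5,
                            pct_convention = "obs",
                            admin_censor_date = as.Date("2016-12-31")) {
  stopifnot(horizon_cap > 0, horizon_cap <= HORIZON_YEARS, quintiles >= 2,
            seed == as.integer(seed))
  structure(list(cohort_path = cohort_path,
                 coefficients_path = coefficients_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_simulate = n_simulate, criteria = criteria,
                 comparators = comparators, horizon_cap = horizon_cap,
                 quintiles = quintiles, pct_convention = pct_convention,
                 admin_censor_date = admin_censor_date),
            class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Executes simulate/load, filter, predict, classify, validate and report
#' in order, writing the report JSON, the table CSV views and a run log
#' (package version, seed, every flag in effect, and the exclusion log).
#' Any stage error aborts with a stage-tagged message and removes partial
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return The `validation_report`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[pcrisk] ", ...)
  written <- character(0)
  stage <- "config"
  result <- tryCatch({
    stage <- "coefficients"
    coefs <- if (is.null(config$coefficients_path)) {
      illustrative_coefficients()
    } else {
      read_coefficients(config$coefficients_path)
    }
    stage <- "cohort"
    truth <- NULL
    if (is.null(config$cohort_path)) {
      say("simulating cohort of ", config$n_simulate)
      bench <- make_benchmark_cohort(config$n_simulate, config$seed,
                                     truth = true_model(coefs))
      raw <- bench$cohort
      truth <- bench$truth
    } else {
      say("reading cohort from ", config$cohort_path)
      raw <- read_cohort_csv(config$cohort_path)
    }
    stage <- "filter"
    filtered <- apply_inclusion_filters(raw, config$criteria)
    say("retained ", filtered$log$n_retained, " of ", filtered$log$n_input,
        " records (", filtered$log$excluded_pct, "% excluded)")
    stage <- "validate"
    report <- run_validation(filtered$cohort, coefs,
                             comparators = config$comparators,
                             quintiles = config$quintiles,
                             horizon_cap = config$horizon_cap,
                             admin_censor_date = config$admin_censor_date,
                             pct_convention = config$pct_convention)
    stage <- "report"
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- write_report(report, config$out_dir)
    labels_path <- file.path(config$out_dir, "risk_labels.csv")
    labels <- do.call(rbind, lapply(config$comparators, function(s) {
      classify_cohort(filtered$cohort, s)
    }))
    utils::write.csv(labels, labels_path, row.names = FALSE)
    written <- c(written, labels_path)
    log_path <- file.path(config$out_dir, "run_log.json")
    jsonlite::write_json(list(
      package_version = as.character(utils::packageVersion("pcrisk")),
      r_version = R.version.string,
      seed = config$seed,
      config = list(cohort_path = config$cohort_path,
                    coefficients_path = config$coefficients_path,
                    n_simulate = config$n_simulate,
                    comparators = config$comparators,
                    horizon_cap = config$horizon_cap,
                    quintiles = config$quintiles,
                    pct_convention = config$pct_convention,
                    admin_censor_date =
                      as.character(config$admin_censor_date),
                    missing_m_as_m0 = config$criteria$missing_m_as_m0,
                    psa_max = config$criteria$psa_max,
                    dx_window = as.character(config$criteria$dx_window),
                    mandatory_fields = config$criteria$mandatory_fields),
      exclusion_log = filtered$log[c("n_input", "n_retained", "n_excluded",
                                     "excluded_pct", "reasons",
                                     "missing_fields")]),
      log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, log_path)
    report
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
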