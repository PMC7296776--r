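#' Construct a coefficient set for the two-cause prognostic model
#'
#' A coefficient set is the full configuration of a PREDICT-style model:
#' log-hazard-scale beta coefficients per cause (prostate cancer, `pc`;
#' other causes, `npc`), the covariate transforms they apply to, annual
#' baseline hazard rates for years 1..15 per cause (piecewise constant),
#' the hazard ratio applied to the prostate-cancer cause under radical
#' treatment, and the biopsy-cores parameterisation mode.
#'
#' Each transform is a list with fields:
#' \describe{
#'   \item{variable}{cohort column the term reads.}
#'   \item{type}{`"identity"` (value minus `center`), `"log"` (natural log
#'     minus `center`), `"indicator"` (1 when the value equals `level`), or
#'     `"ppc"` (proportion of positive cores, interpreted per `ppc_mode`).}
#'   \item{center}{numeric offset subtracted after the transform
#'     (default 0).}
#'   \item{level}{category matched by an indicator term.}
#' }
#'
#' @param betas List with elements `pc` and `npc`, each a named numeric
#'   vector of coefficients keyed by term name.
#' @param transforms Named list of transform descriptions, one per term
#'   referenced by any beta.
#' @param baseline_hazard List with elements `pc` and `npc`, each a numeric
#'   vector of 15 non-negative annual hazard rates.
#' @param radical_hr_pc Positive hazard ratio multiplying the
#'   prostate-cancer cause hazard under the radical-treatment scenario.
#' @param ppc_mode One of `"excluded"` (biopsy term dropped),
#'   `"dichotomous_50"` (indicator of PPC >= 0.5) or `"continuous"`
#'   (fraction used directly).
#' @param adt_hr_pc Optional multiplier on the prostate-cancer hazard for
#'   men on androgen deprivation monotherapy under the as-treated scenario
#'   (the underlying tool models conservative vs radical only; default 1
#'   evaluates ADT men with conservative-scenario hazards).
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(betas, transforms, baseline_hazard,
                            radical_hr_pc = 1,
                            ppc_mode = c("excluded", "dichotomous_50",
                                         "continuous"),
                            adt_hr_pc = 1) {
  ppc_mode <- match.arg(ppc_mode)
  stopifnot(is.list(betas), all(c("pc", "npc") %in% names(betas)),
            is.list(baseline_hazard),
            all(c("pc", "npc") %in% names(baseline_hazard)))
  for (cause in c("pc", "npc")) {
    h0 <- baseline_hazard[[cause]]
    if (length(h0) != HORIZON_YEARS) {
      stop("baseline_hazard$", cause, " must have exactly ",
           HORIZON_YEARS, " annual values")
    }
    if (anyNA(h0) || any(h0 < 0)) {
      stop("baseline_hazard$", cause, " must be non-negative")
    }
    b <- betas[[cause]]
    if (length(b) > 0 && is.null(names(b))) {
      stop("betas$", cause, " must be a named numeric vector")
    }
    missing_tr <- setdiff(names(b), names(transforms))
    if (length(missing_tr) > 0) {
      stop("beta term(s) without a declared transform: ",
           paste(missing_tr, collapse = ", "))
    }
  }
  if (!is.numeric(radical_hr_pc) || radical_hr_pc <= 0) {
    stop("radical_hr_pc must be > 0")
  }
  if (!is.numeric(adt_hr_pc) || adt_hr_pc <= 0) stop("adt_hr_pc must be > 0")
  for (nm in names(transforms)) {
    tr <- transforms[[nm]]
    if (is.null(tr$variable) ||
        !tr$type %in% c("identity", "log", "indicator", "ppc")) {
      stop("transform '", nm, "' needs a variable and a type in ",
           "identity/log/indicator/ppc")
    }
  }
  structure(list(betas = lapply(betas[c("pc", "npc")], unlist),
                 transforms = transforms,
                 baseline_hazard = lapply(baseline_hazard[c("pc", "npc")],
                                          as.numeric),
                 radical_hr_pc = radical_hr_pc,
                 ppc_mode = ppc_mode,
                 adt_hr_pc = adt_hr_pc),
            class = "coefficient_set")
}

#' Read / write a coefficient set as JSON
#'
#' The JSON layout mirrors the constructor:
#' `{"betas": {"pc": {...}, "npc": {...}}, "transforms": {...},
#'   "baseline_hazard": {"pc": [15 numbers], "npc": [15 numbers]},
#'   "radical_hr_pc": x, "ppc_mode": "...", "adt_hr_pc": x}`.
#'
#' @param path File path.
#' @return `read_coefficients` returns a `coefficient_set`;
#'   `write_coefficients` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefficient_set(betas = lapply(x$betas, unlist),
                  transforms = x$transforms,
                  baseline_hazard = x$baseline_hazard,
                  radical_hr_pc = x$radical_hr_pc,
                  ppc_mode = x$ppc_mode,
                  adt_hr_pc = if (is.null(x$adt_hr_pc)) 1 else x$adt_hr_pc)
}

#' @rdname read_coefficients
#' @param coefs A `coefficient_set`.
#' @export
write_coefficients <- function(coefs, path) {
  stopifnot(inherits(coefs, "coefficient_set"))
  out <- unclass(coefs)
  out$betas <- lapply(out$betas, as.list)  # keep term names in the JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Illustrative coefficient set
#'
#' The published validation does not print the underlying model's
#' coefficients or baseline hazards (they belong to the model development
#' study); the engine is therefore configuration-driven.  This bundled set
#' is *illustrative*: its structure matches the real tool (age and log-PSA
#' terms, grade-group and stage indicators and a biopsy term on the cancer
#' cause; age and comorbidity on the other-cause hazard) and its magnitudes
#' are chosen so that a synthetic registry cohort reproduces baseline-table
#' crude mortality rates (about 1.4 and 4.4 deaths per 100 person-years).
#' It is suitable for demonstrations, simulations and tests, not for
#' clinical prediction.
#'
#' @return A `coefficient_set`.
#' @export
illustrative_coefficients <- function() {
  transforms <- list(
    age_c   = list(variable = "age_dx", type = "identity", center = 65),
    lpsa    = list(variable = "psa", type = "log", center = log(10)),
    gg2     = list(variable = "grade_group", type = "indicator", level = 2),
    gg3     = list(variable = "grade_group", type = "indicator", level = 3),
    gg4     = list(variable = "grade_group", type = "indicator", level = 4),
    gg5     = list(variable = "grade_group", type = "indicator", level = 5),
    t2      = list(variable = "t_stage", type = "indicator", level = "T2"),
    t3      = list(variable = "t_stage", type = "indicator", level = "T3"),
    t4      = list(variable = "t_stage", type = "indicator", level = "T4"),
    comorb  = list(variable = "comorbid", type = "indicator", level = TRUE),
    ppc     = list(variable = "ppc", type = "ppc")
  )
  betas <- list(
    pc = c(age_c = 0.030, lpsa = 0.35, gg2 = 0.55, gg3 = 1.05, gg4 = 1.55,
           gg5 = 2.15, t2 = 0.35, t3 = 0.85, t4 = 1.30, ppc = 0.90),
    npc = c(age_c = 0.090, comorb = 0.65)
  )
  u <- seq_len(HORIZON_YEARS)
  baseline_hazard <- list(
    # cancer-cause baseline: low early, slowly rising
    pc = 0.0035 + 0.00024 * u,
    # other-cause baseline for a healthy 65-year-old, rising ~5%/year
    npc = 0.0129 * 1.05^(u - 1)
  )
  coefficient_set(betas = betas, transforms = transforms,
                  baseline_hazard = baseline_hazard,
                  radical_hr_pc = 0.65, ppc_mode = "excluded",
                  adt_hr_pc = 1)
}
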