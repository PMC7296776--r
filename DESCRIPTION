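Package: pcrisk
Title: External Validation of Competing-Risks Prognostic Models for
    Non-Metastatic Prostate Cancer
Version: 0.1.0
Authors@R:
    person("PCRisk", "Developers", email = "pcrisk@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate and externally validate PREDICT-style
    two-cause (prostate-cancer-specific and other-cause) prognostic models
    on registry-like cohorts.  Provides a configuration-driven risk engine
    computing prognostic indices, annual piecewise-constant cause-specific
    hazards and exact competing-risks cumulative incidence over 15 years;
    comparator risk classifiers (UCSF CAPRA points, EAU 3-stratum and an
    NCCN-style stratification); Harrell's concordance index with jackknife
    standard errors and paired model comparisons; observed-to-expected
    calibration across risk quintiles and treatment subgroups with a
    grouped chi-square goodness-of-fit test; and a synthetic cohort
    generator with known ground-truth hazards so that every stage of the
    pipeline is testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
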