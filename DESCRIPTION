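Package: vaval
Title: Validation of Verbal Autopsy Cause-of-Death Assignment for Neonatal Deaths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating verbal autopsy (VA) diagnoses of neonatal
    cause of death against a clinical reference standard. Implements the
    age- and gestation-stratified hierarchy for assigning a single primary
    cause of death from case-definition eligibility flags, dual-reviewer
    plus arbiter adjudication with an "unclassifiable" rule, per-cause
    diagnostic accuracy (sensitivity, specificity, predictive values) with
    Wilson score confidence intervals, cause-specific mortality fraction
    (CSMF) tables, chi-square comparisons, and a synthetic cohort generator
    that emulates the misclassification and reviewer-agreement structure of
    a hospital-based VA validation study, so the full pipeline is testable
    without access to patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
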