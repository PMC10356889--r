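Package: cbmndose
Title: Radiation Biodosimetry with the Cytokinesis-Block Micronucleus Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cytogenetic radiation biodosimetry based on the
    cytokinesis-block micronucleus (CBMN) assay. Fits linear-quadratic
    dose-response calibration curves to micronucleus yields by Poisson
    maximum likelihood, estimates absorbed dose from observed micronucleus
    counts with 95% confidence limits that merge Poisson counting error and
    calibration-curve uncertainty, quantifies and corrects automated-scoring
    errors (false-positive binucleated cells, false-positive and
    false-negative micronuclei), computes triage classification metrics at a
    clinical dose cutoff, and simulates complete seeded CBMN experiments
    including a dose-dependent scoring-error corruption model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
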