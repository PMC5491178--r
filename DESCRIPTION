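Package: celiacclaims
Title: Validation of Claims-Based Case Ascertainment for Pediatric Celiac
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and validating case-ascertainment algorithms
    for biopsy-proven pediatric celiac disease in linked health-administrative
    data. Provides a linked-claims data model (population registry, outpatient
    physician claims, same-day-surgery procedure records, hospital discharges,
    physician specialties), a synthetic-cohort generator with known ground
    truth, a declarative grid of endoscopy-plus-contact algorithms, diagnostic
    accuracy statistics with continuity-corrected score confidence intervals,
    weighted kappa for rater agreement, directly age-sex standardized incidence
    with Gamma-method confidence intervals, and Poisson regression for annual
    percent change in incidence.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
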