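Package: cvdcalib
Title: Calibration of Cardiovascular Risk Equations in Cohorts with Severe
    Mental Illness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for external validation of sex-specific Cox-form
    cardiovascular risk equations in linked electronic-health-record
    cohorts, with a focus on people treated by specialist mental health
    services. Provides a synthetic linked-cohort generator (person and
    service-contact tables with configurable excess event risk in the
    exposed group), absolute-risk scoring from declarative equation
    specifications, eligibility and exposure ascertainment with full flow
    accounting, Kaplan-Meier observed risk with Greenwood confidence
    bands, directly age-standardized cumulative-incidence curves, and
    decile-based observed:predicted calibration with the mean-ratio
    summary statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
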