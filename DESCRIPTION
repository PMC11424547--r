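Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection
    in FAERS-style spontaneous adverse event report databases. Parses the
    quarterly dollar-delimited ASCII dialect (DEMO, DRUG, REAC, OUTC, THER),
    deduplicates reports at the case and key-field levels, selects
    primary-suspect reports for a target drug, builds report-level 2x2
    contingency tables at the MedDRA preferred-term and system-organ-class
    levels, and computes four disproportionality statistics: the reporting
    odds ratio (ROR), the proportional reporting ratio (PRR) with the Pearson
    chi-squared statistic, the Bayesian confidence propagation neural network
    information component (BCPNN IC), and the multi-item gamma-Poisson
    shrinker empirical Bayes geometric mean (MGPS EBGM). Consensus screening,
    ranking, demographic and time-to-onset summaries, serious versus
    non-serious contrasts and pediatric-versus-adult subgroup analyses mirror
    standard published FAERS workflows. A synthetic report generator with
    planted reporting-rate ratios, injected duplicates and configurable
    missingness makes every stage testable without access to the real
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
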