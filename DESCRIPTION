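Package: ciclovia
Title: Urban Segregation and Socioeconomic Exposure Analysis for Open-Streets Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether open-streets (Ciclovia Recreativa) programs
    let participants traverse socioeconomic environments unlike their area of
    origin. Implements entropy-based evenness indices of urban segregation
    (per-unit entropy scores and the metropolitan Theil index), shortest-path
    trajectories over a street network, 500-m socioeconomic-status (SES)
    exposure profiles with maximum SES-percentile-difference statistics and a
    permutation test, route overlays on an SES tessellation, harmonization of
    multi-city intercept surveys (SES codings, WHO physical-activity guideline
    classification, BMI, self-rated health, safety perception), descriptive
    tables with Pearson chi-squared tests, and a two-level logistic model with
    a city random intercept. A seeded synthetic-city generator provides
    geographies, street networks, routes, participants and city-dialect raw
    surveys with the statistical structure the analysis assumes, so the whole
    pipeline is testable without restricted survey or GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    igraph,
    lme4,
    jsonlite,
    yaml,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
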