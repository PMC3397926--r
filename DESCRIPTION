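Package: shearwaterCMR
Title: Capture-Mark-Recapture Survival Analysis for a Long-Lived Migratory Seabird
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cormack-Jolly-Seber survival analysis for long-term annual
    capture-recapture monitoring of a long-lived seabird colony, including
    goodness-of-fit decomposition into transience and trap-dependence
    components, first-encounter suppression, Markovian trap-dependent
    capture models with fixed-zero capture masks for monitoring gaps,
    overdispersion-adjusted QAICc model selection, analysis-of-deviance
    (ANODEV) testing of environmental and fishery covariates, a deviance
    R-squared effect-size statistic, seasonal reduction of monthly
    environmental series into standardized annual covariates, and a
    simulation module generating capture histories and covariate series
    with the statistical structure the analysis assumes.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
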