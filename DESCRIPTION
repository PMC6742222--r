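Package: heicohort
Title: Healthy Eating Index Scoring and Mother-Offspring Diet-Quality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores diet quality with an eight-component Danish Healthy
    Eating Index (0-80 points; fruits and vegetables, dietary fibre, fish,
    red meat, saturated fat, sodium, sugar-sweetened beverages, added
    sugar) from quantified food-frequency-questionnaire intakes, and
    provides the full two-generation cohort pipeline built around it:
    exclusion flows, quartile ranking, log-linear binomial relative-risk
    models with median-coded trend tests, stratified and sensitivity
    analyses, correlation panels, attrition comparison, and a calibrated
    Gaussian-copula simulator of mother-offspring intake pairs so every
    stage can be exercised without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
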