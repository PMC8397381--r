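Package: tcrad
Title: Traditional Costa Rican Adolescents Diet Score Construction and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates the Traditional Costa Rican Adolescents Diet
    (TCRAD) score, a 14-component binary adherence index scored against
    sex-specific median intake cutoffs. Provides readers for tabular 3-day
    food records, a synthetic food-record cohort generator with realistic
    between- and within-person variance structure, pre-scoring steps
    (sex-specific energy-outlier exclusion at the 1st/99th percentiles,
    usual-intake estimation by person means or one-way shrinkage, energy
    adjustment by the residual method), the scoring engine with score and
    socioeconomic-status category rules, and a validation battery of
    score-nutrient Spearman correlations, category-wise component medians
    with pairwise rank-sum comparisons, sociodemographic stratum summaries,
    and category-proportion crosstabs.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
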