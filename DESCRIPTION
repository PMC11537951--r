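Package: temkit
Title: Reliability Assessment for Anthropometric Standardisation Exercises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies intra- and inter-rater measurement reliability in
    anthropometric survey standardisation exercises. Computes the pooled
    technical error of measurement (TEM) and its derived statistics (relative
    TEM, coefficient of reliability R), the one-way random-effects intraclass
    correlation coefficient for unbalanced multi-rater designs, F-based
    comparisons of TEM between rater groups, and Bland-Altman agreement
    analyses in both intra-rater and inter-rater constructions. A stratified
    reporting pipeline assembles these statistics by parameter, rater group
    and volunteer age group, and a synthetic measurement generator with known
    variance components supports validation and parameter-recovery studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
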