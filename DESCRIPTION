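Package: equisplit
Title: Splitting Samples into Equivalent Subsamples for Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dividing a participants-by-items response matrix into
    subsamples that are equivalent in their common variance, as needed for
    exploratory/confirmatory factor-analysis cross-validation. Implements the
    Solomon method (ordering participants by a variance-weighted composite of
    principal-component projections and assigning them alternately), the
    Duplex max-min Euclidean distance comparator, random splitting, k-way and
    stratified extensions, the Kaiser-Meyer-Olkin sampling-adequacy statistic,
    and the Communality Ratio S that scores how equivalent two subsamples are.
    Includes a Monte-Carlo simulation toolkit that generates factor-model
    populations, continuous and 5-point categorized samples, and runs the
    method-comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
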