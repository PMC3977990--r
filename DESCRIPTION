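Package: gamet
Title: Genetic Association Meta-Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of genetic association studies of a
    biallelic variant, built around the KCNJ11 E23K (rs5219) / type 2
    diabetes literature. Reconstructs per-study 2x2 contingency tables under
    allele, heterozygous, homozygous, dominant and recessive genetic models,
    pools log odds ratios by fixed-effect and DerSimonian-Laird
    random-effects methods with Cochran Q, tau-squared and I-squared
    heterogeneity summaries, stratifies by ethnicity and sample size with
    between-subgroup heterogeneity tests, combines case-control and
    family-based (transmission disequilibrium) designs, runs
    method-of-moments meta-regression with proportion-of-heterogeneity
    explained, Egger small-study regression and funnel coordinates,
    leave-one-out sensitivity, population attributable risk and
    power/sample-size calculations. Ships the 48-study summary table as a
    packaged fixture and a synthetic-study simulator with known truth for
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
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
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
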