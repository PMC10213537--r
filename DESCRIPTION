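Package: manuremeta
Title: Meta-Analysis of Manure Substitution Effects on Crop Yield and
    Nitrogen Use Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesising paired field-trial comparisons of
    synthetic nitrogen fertilizer (NPK) against partial or full replacement
    of synthetic N with animal manure (NPKM) at equal total N input.
    Implements log response-ratio effect sizes with inverse-variance
    pooling and 95% confidence intervals, subgroup (moderator) analysis
    over management, climate and soil variables, random-forest permutation
    importance of moderators, and dose-response curve fitting with
    optimum and threshold extraction. Includes a synthetic
    literature-database generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
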