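Package: sehybrid
Title: Hybrid Gut-Microbiome Modeling of Selenium Absorption Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual selenium-absorption efficiency (low vs.
    high) from pre-intervention gut-microbiome genus profiles and host
    metadata. Provides gradient-boosted biomarker ranking with
    learning-curve refinement, one-hot encoding and L2-normalized fusion
    of host covariates, hybrid cross-batch model calibration, and
    cross-cohort shared-feature screening, together with alpha/beta
    diversity statistics (Shannon, Simpson, Chao1, Bray-Curtis,
    one-factor PERMANOVA) and a synthetic multi-batch, multi-region
    cohort generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    vegan,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
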