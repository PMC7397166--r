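Package: itoensemble
Title: Two-Phase Heterogeneous Ensemble Classification for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-accuracy-high-reliability binary classifiers for
    high-dimension low-sample-size expression data using infiltration-tactics
    optimization: a fast first wave of parameter-free classifiers (LIG) and a
    grid-tuned second wave (FT), each trained under randomly sampled attack
    vectors (preprocessing x feature selection x subset size x validation),
    ranked by the efficiency index rho = MCC x accuracy, filtered by an
    epsilon threshold, and combined by greedy non-deteriorating majority-vote
    ensembling. Includes mutual-information feature selection (mRMR, JMI,
    JMIM), quantile/robust/standard scaling, a seeded synthetic-data
    generator for planted-feature benchmarks, and tidy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
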