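Package: txage
Title: Transcriptional Age and Differential Expression Analysis for PBMC
    Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for case/control bulk RNA-seq cohort
    analysis in peripheral blood mononuclear cells (PBMCs): a
    negative-binomial Wald differential-expression engine with
    median-of-ratios normalisation, method-of-moments dispersion shrinkage
    and Cook's-distance outlier handling; marginal screening of clinical
    covariates for confounding; estimation of expected false positives by
    repeated differential expression on randomised case/control labels with
    hypergeometric over-representation of recurrent false positives;
    topological-overlap co-expression clustering with metagene group tests;
    and a transcriptional biological-age score (sign-aligned mean z-score
    over an age-associated gene signature) with a regression-residual
    Fisher exact asymmetry test between groups. Includes a seeded
    negative-binomial count simulator with planted covariate, cluster and
    ageing effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
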