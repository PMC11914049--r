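Package: reefstats
Title: Statistical Pipeline for Long-Term Coral Community Recovery Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-decadal benthic cover surveys of coral
    communities on artificial structures and natural reefs, and the carbonate
    chemistry of artificial tide pools. Resolves semi-quantitative cover
    records ("R", "+", ranges) to percent cover, applies compositional
    log-ratio transforms with multiplicative zero replacement, fits
    hierarchical Bayesian effect-size models for cover and colony counts with
    highest-density-interval credibility classification, runs robust Aitchison
    ordination and permutational multivariate ANOVA, fits penalized
    thin-plate-spline environmental response curves, and estimates net
    ecosystem calcification from total-alkalinity drawdown in stagnant tide
    pools with delta-method error propagation. Includes seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
Suggests:
    emmeans,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
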