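Package: rhizoniche
Title: Global Niche and Distribution Modelling for Rhizostome Jellyfishes from Presence-Only Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for predicting global ecological niches and
    distributions of rhizostome jellyfish genera from presence-only occurrence
    reports paired with gridded monthly ocean climatology. Includes rarefied
    sample-coverage screening of occurrence data, spatiotemporal pairing of
    reports with environmental fields, multivariate negative-binomial GLM niche
    testing with permutation inference, per-genus random-forest models with
    largest-Gini-gap predictor selection, inner-90th-percentile environmental
    envelope habitat prediction, and evaluation against independent legacy
    occurrence records. A synthetic-data module generates environmental fields,
    niche-driven reports, and legacy samples with the statistical structure the
    analysis assumes, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    ggplot2,
    MASS,
    randomForest,
    vegan,
    igraph,
    yaml,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
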