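Package: clgc
Title: Climate-Change Landscape Genetics and Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end landscape-genetics toolkit for projecting the
    impact of climate change on the range, connectivity, genetic diversity
    and genetic clusters of a species. Provides ensemble species
    distribution modelling with TSS/AUC model gating and lowest-presence
    threshold binarization, range-shift accounting, friction-based
    least-cost-path connectivity networks, microsatellite and chloroplast
    haplotype diversity statistics with persistence-based future
    projection, Mantel and partial Mantel matrix permutation tests, a
    climate-covariate Bayesian admixture model fitted by MCMC with
    DIC-based cluster selection and future ancestry projection, inverse
    distance weighted genetic-divergence landscapes regressed on climatic
    stability with generalized additive models, and a seeded synthetic-data
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    geosphere,
    mgcv,
    nnet,
    rpart,
    MASS,
    randomForest,
    pROC,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
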