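Package: nichecast
Title: Ensemble Species Distribution Modeling and Richness Hotspot Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for ensemble species distribution
    modeling (SDM) and stacked-richness hotspot change analysis, built for
    presence-only occurrence data of Himalayan medicinal and aromatic plants
    but applicable to any multi-species study. Provides occurrence cleaning
    (deduplication, elevation-range sanity filtering, one-record-per-cell
    spatial thinning), pairwise-correlation pruning of bioclimatic predictors,
    multi-GCM climate ensembles, per-species ensembles of seven learners over
    three pseudo-absence sets and three evaluation runs scored by the True
    Skill Statistic (TSS), TSS-weighted ensemble predictions binarized at the
    max-TSS threshold, stacked species richness, extent and top-quartile
    hotspot maps, zonal change accounting (ecoregions, protected areas,
    provinces, physiography, elevation bands), summary reporting, and a
    virtual-species synthetic-data generator for end-to-end validation against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    nnet,
    rpart,
    randomForest,
    xgboost,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
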