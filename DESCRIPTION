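Package: micromat
Title: Longitudinal Microbiome and Metabolome Statistics for Sow-Piglet Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for longitudinal 16S feature-table and
    untargeted-metabolome studies of early-life gut microbiota. Provides
    feature-table preprocessing (rarefaction, abundance/prevalence filtering,
    taxonomic collapsing), alpha/beta diversity with PERMANOVA and the
    Scheirer-Ray-Hare rank test, LEfSe-style differential abundance with
    bootstrap LDA effect sizes, SparCC compositional correlation networks with
    topology metrics and bootstrap Kolmogorov-Smirnov network comparison,
    biweight-midcorrelation coabundance module detection with eigenmetabolites,
    OPLS-DA with VIP-based metabolite selection, random-forest microbiota-age
    modelling with relative-maturity scoring, co-inertia analysis with the RV
    coefficient, genus-level redundancy analysis, and an mRMR/SVM diarrhea
    classifier with incremental feature selection. A synthetic-data module
    generates cohorts with planted, recoverable structure so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    permute,
    MASS,
    randomForest,
    e1071,
    pROC,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
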