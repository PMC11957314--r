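Package: phenotox
Title: Phenotypic Profiling and Cytotoxicity Prediction for Cell Painting
    Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of Cell Painting high-content screens in
    which a compound panel is profiled across concentrations against
    vehicle controls. Single-cell morphological feature tables are
    aggregated to per-well median profiles and cell counts, normalized
    per plate against vehicle wells (Robust MAD, Z-score or min-max),
    and pruned by variance and correlation filters. Treatment-level
    profiles carry an induction statistic (fraction of features with
    absolute robust Z-score above 3) used to screen out weak
    perturbations before hierarchical clustering on Pearson
    dissimilarities. Random-forest regressors predict ATP-based
    viability and cell count from morphology, per compound and
    globally, with a from-scratch SMOGN implementation to oversample
    rare cytotoxic profiles. Dose-response utilities provide
    vehicle-relative viability normalization, Welch significance
    screens of count and viability, detection of count/ATP decoupling,
    and four-parameter log-logistic IC50/LC50 summaries. A synthetic
    plate generator with known ground truth emulates the full design
    (compound mechanisms, Hill-curve toxicity, plate effects) so every
    stage is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    minpack.lm,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: CellBasedAssays, Regression, Clustering, Software
RoxygenNote: 7.3.3
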