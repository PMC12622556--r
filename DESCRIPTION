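Package: phenoscore
Title: Interpretable Per-Cell Phenotype Association Scores from Neighborhood Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies a sample-level clinical phenotype from single-cell data by
    diffusing cells over a k-nearest-neighbour graph into a sample-by-neighborhood
    abundance matrix, reducing it to latent abundance dimensions (PCA or NMF, with
    optional linear batch adjustment), fitting tree-ensemble classifiers under
    repeated nested cross-validation with randomized hyperparameter search, and
    attributing each prediction to model features with exact path-dependent
    TreeSHAP. Per-cell Shapley attributions are averaged over repeats, collapsed
    across classes, and summed into an Interpretable Score that quantifies each
    cell's contribution to the predicted phenotype, including contributions from
    covariate and latent-dimension-by-covariate interaction terms. Ships a
    Gaussian variance-partition single-cell simulator with controlled per-factor
    variance fractions, fold-change-driven differential cluster abundance, rare
    clusters, and condition-by-sex interaction effects, together with downstream
    marker-correlation, cluster-summary, and detection-accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    ranger,
    jsonlite,
    cluster,
    limma,
    BiocNeighbors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    xgboost,
    optparse,
    withr
Config/testthat/edition: 3
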