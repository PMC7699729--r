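Package: connectoscore
Title: Generalized Cognitive Scores from Structural Connectomes with
    Stability-Selected Network Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links the topology of weighted structural brain connectomes to a
    data-driven generalized cognitive score. Computes node-level graph metrics
    (strength, eigenvector centrality, local efficiency) from streamline-count
    connectivity matrices, derives a composite cognitive score as the
    leakage-free first principal component of a clinical battery inside each
    cross-validation fold, validates the score by Gaussian-mixture clustering
    against diagnostic labels with a permutation-tested normalized mutual
    information, regresses connectivity features on the score with the Lasso
    tuned on inner validation splits, and aggregates the sparse weights across
    repeated cross-validation rounds into frequency-based stability-selected
    biomarker lists. Includes a synthetic-cohort generator with a planted
    latent severity factor so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    igraph,
    e1071,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Clustering, Regression,
    FeatureExtraction, DimensionReduction
RoxygenNote: 7.3.3
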