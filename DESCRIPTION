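Package: celldyn
Title: Cross-Age Transcriptomic Dynamics and Spatial Ligand-Receptor
    Colocalization for Developmental Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how strongly cell-subtype transcriptomic identities
    reorganize across a developmental time course. A supervised classifier is
    trained on the subtype labels of one age and used to classify cells of the
    next age; the dynamic score, one minus the Rand index between the true and
    transferred subtype partitions, measures per-class transcriptomic
    reorganization between consecutive ages, and row-normalized confusion
    matrices give Sankey-style correspondence edges between ages. Also
    provides the supporting single-cell toolkit: quality-control filters,
    library-size log-normalization, dispersion-based highly variable gene
    selection, Wilcoxon rank-sum differential expression with a log2
    fold-change threshold, subtype proportion time courses, k-nearest-neighbor
    ligand-receptor spatial colocalization scoring for segmented cell fields,
    argmax spot annotation for deconvolution abundances, and a
    negative-binomial multi-age simulator with controllable expression-program
    drift for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp,
    xgboost,
    glmnet,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
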