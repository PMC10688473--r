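Package: gainloss
Title: Gain- and Loss-of-Function Variant Classification from Tabular,
    Structural and Network Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for labelling pathogenic variants as gain-of-function
    (GOF) or loss-of-function (LOF) from publication abstracts, assembling
    gene-disjoint stratified datasets with homology filtering, deriving
    residue-level features from predicted protein structures (contacts,
    centre-of-mass distances, solvent accessibility, 3D variant density),
    embedding protein-protein interaction networks with biased random
    walks and skip-gram, training soft-voting ensembles of
    gradient-boosted tree classifiers under gene-grouped nested
    cross-validation, calibrating per-gene prediction intervals by
    Kolmogorov-Smirnov distribution selection, and downstream enrichment
    and Firth-penalized association testing. Includes synthetic-data
    generators with known ground truth for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
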