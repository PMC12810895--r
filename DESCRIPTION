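Package: tcrHLA
Title: HLA Genotype Inference from TCR-Beta Repertoires
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery of exact and near-exact (edit-distance-1)
    HLA-associated TCR-beta features across immune repertoires, per-allele
    L1-regularized logistic classifiers with inverse-probability class
    weighting, Platt and diversity-adjusted probability calibration with
    confidence gating, and meta-clonotype discovery in repertoires with
    imputed HLA genotypes. Includes a synthetic cohort generator with
    planted public and quasi-public allele-linked clonotypes for
    benchmarking every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    jsonlite,
    igraph,
    glmnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Classification, ImmunoOncology, StatisticalMethod
RoxygenNote: 7.3.3
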