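Package: sccaRepo
Title: Sparse Canonical Correlation Analysis for Drug Repositioning with
    Integrated Molecular Targets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts correlated sets of molecular targets (proteins,
    miRNAs, lncRNAs) and disease indications from paired binary
    drug-target and drug-disease incidence matrices by sparse canonical
    correlation analysis, solved through rank-one penalized matrix
    decomposition with iterative deflation. Predicts new indications for
    drugs by linearly combining the extracted canonical components
    weighted by their canonical correlations. Includes repeated k-fold
    cross-validation with pooled ROC/AUC evaluation, a Jaccard-similarity
    collaborative-filtering baseline, a planted-component synthetic data
    generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StatisticalMethod, DimensionReduction, Pharmacogenomics
RoxygenNote: 7.3.3
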