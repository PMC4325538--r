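Package: genesettr
Title: Cross-Species Prediction of Gene Set Activation from Replicate
    Microarray Data
Version: 0.1.0
Authors@R: person("genesettr", "developers", role = c("aut", "cre"),
    email = "maintainers@genesettr.dev")
Description: Predicts differential gene-set enrichment in human bronchial
    epithelial cells from measurements in rat cells exposed to the same
    stimuli.  Provides replicate-based microarray noise modelling with a
    universal noise curve, iterative outlier removal, saturation-curve
    reconstruction by integration and signal linearization; differential
    calls with curve-derived standard deviations; binary activation calling
    of gene-set NES/FDR matrices; mutual-information screening of ortholog
    pairs with permutation significance; a PCA-reduced pooled-diagonal
    Gaussian classifier with empirical priors and leave-one-out ensembling;
    challenge-style evaluation metrics (AUPR, AUROC, BAC, MCC) with a
    stratified resampling robustness check; and a synthetic-data generator
    that emulates the statistical structure the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
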