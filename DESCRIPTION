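Package: histoepi
Title: Histoepigenetic Deconvolution and Gene-Network Analysis of Bulk Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage histoepigenetic analysis of bulk tumor profiles.
    Stage one performs reference-guided epigenomic deconvolution of DNA
    methylation beta values by constrained alternating least squares,
    estimates cell-type-specific expression by proportion-conditioned
    regression, and partitions samples by the cancer-cell-intrinsic
    expression of a gene of interest with an iterative group-fit algorithm,
    multi-run consensus and recursive splitting. Stage two places the gene
    in a sparse Gaussian graphical model fitted over log2 expression with
    cell-proportion covariate nodes, selects the penalty by stability
    (StARS), strips the covariate nodes, and scores module connectedness by
    a permutation edge-count statistic and edge enrichment by
    hypergeometric tests. A paired methylation/expression mixture simulator
    with ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
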