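Package: neuroGREML
Title: SNP Heritability of Brain Responses and Functional-Network Structure
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for estimating SNP-based heritability of
    regional brain responses to facial expressions and relating those
    estimates to properties of the face-processing network. Provides
    genotype quality control in PLINK text formats, genomic relationship
    matrix (GRM) construction in GCTA conventions, univariate and bivariate
    average-information REML variance-component estimation with a
    boundary-mixture likelihood-ratio test, block-design functional
    connectivity graphs with nodal degree, a Monte-Carlo correlated
    count-of-significant-tests null, trend regressions, and a synthetic-data
    generator with known ground truth that makes every stage testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
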