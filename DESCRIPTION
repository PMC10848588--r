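Package: gskit
Title: Genomic Prediction with Pedigree, Genomic, Single-Step and Bayesian Marker Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genomic-evaluation toolkit for quantitative traits in
    pedigreed, partially genotyped populations. Provides simulation of
    crossbred populations (founder lines with linkage disequilibrium,
    gene dropping with recombination, configurable trait architectures),
    genotype input/output (PLINK bed/bim/fam and VCF) with standard
    marker quality control, pedigree (A), genomic (VanRaden G) and
    single-step blended (H inverse) relationship matrices,
    average-information REML variance-component estimation, Henderson
    mixed-model equations for BLUP, GBLUP and single-step GBLUP, Gibbs
    samplers for five Bayesian marker-effect models (BayesB, BayesCpi,
    BayesN, BayesS, BayesR), and cross-validated prediction-reliability
    evaluation including marker-density subsampling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
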