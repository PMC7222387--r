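Package: ssgblup
Title: Single-Step Genomic Evaluation with Pedigree and Genomic Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-step genomic best linear unbiased prediction
    (ssGBLUP) in livestock genetic evaluation. Builds the pedigree numerator
    relationship matrix A and its sparse inverse (Henderson's rules with
    inbreeding via the Meuwissen-Luo recursion), the VanRaden genomic
    relationship matrix G from quality-controlled SNP genotypes, and the
    combined pedigree-genomic matrix H and its inverse. Variance components
    and breeding values are estimated with Gibbs samplers for linear and
    threshold (liability) animal models with a random flock effect.
    Includes breeding-value accuracy from prediction error variance, the
    Geweke convergence diagnostic, model comparison reports, and a
    synthetic-data generator (multi-generation pedigrees, gene-dropped SNP
    genotypes, continuous and ordinal phenotypes) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
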