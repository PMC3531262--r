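Package: imputeBench
Title: Simulation-Based Benchmarking of SNP Genotype Imputation and Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genotype imputation strategies in pedigreed
    livestock populations. Simulates multi-generation pedigrees with
    linkage-disequilibrium-structured haplotypes and daughter-trait-deviation
    phenotypes, constructs nested SNP panels of different densities by quality
    control and iterative even-spacing thinning, imputes masked genotypes with
    a diploid haplotype-copying hidden Markov model (including a multi-tier
    reference framework and an allele-frequency sampling baseline), scores
    imputation by allelic and genotypic error rates stratified by pedigree
    kinship, and quantifies the downstream effect of imputed genotypes on the
    accuracy of genomic prediction with a reliability-weighted SNP-BLUP.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
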