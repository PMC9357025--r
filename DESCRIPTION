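Package: ancientmix
Title: Mixed-Stock Analysis of Ancient DNA SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic stock identification (GSI) of low-coverage
    ancient-DNA samples genotyped at small biallelic SNP panels. Provides
    genotype table input/output (wide CSV and genepop), replicate-genotyping
    concordance and missingness QC, per-collection diversity statistics
    (Ho, He, F_IS), pairwise Weir-Cockerham F_ST with permutation tests,
    biallelic Hardy-Weinberg exact tests, genotypic linkage-disequilibrium
    tests, PCA of allele dosages, a Bayesian conditional mixture model
    (Gibbs sampler) estimating mixing proportions of reference collections
    and reporting groups, leave-one-out and simulation-based assessment of
    assignment accuracy, and a synthetic-data generator emulating an
    archaeological mixed-stock study design.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
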