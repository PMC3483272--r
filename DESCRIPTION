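Package: homogwas
Title: Cohort Homogenization for Population-Structure Correction in
    Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Corrects for population stratification in case-control
    genome-wide association studies by homogenizing the diseased/healthy
    phenotype ratio across the cohort. Selected subjects have their
    statistical weight iteratively knocked down so that, locally in
    principal-component ancestry space, the phenotype ratio becomes
    uniform and null genotypes tagging a subpopulation can no longer
    masquerade as associated. Provides weighted 2x2 contingency tables
    with odds-ratio and Fisher exact testing, subject-centered
    weight-characterized spheres in PC space, the iterative knock-down
    homogenization algorithm, the potential p-value bias diagnostic,
    LD pruning and PCA construction of the ancestry space, four
    association-testing strategies with ROC comparison, and a synthetic
    cohort/genotype simulator for validating the method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
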