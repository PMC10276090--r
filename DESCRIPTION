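Package: triopgs
Title: Trio-Based Polygenic Score Analysis of Comorbid Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for trio-based polygenic score (PGS) analyses of
    comorbid phenotypes in ascertained proband samples. Harmonizes GWAS
    summary statistics against a target genotype panel, computes PGS at
    multiple p-value thresholds and aggregates them by principal component
    analysis (PGS-PCA), performs the polygenic transmission disequilibrium
    test (pTDT) comparing proband scores to the mid-parent expectation with
    cross-cohort pooling, and fits case-only logistic associations between
    PGS and binary outcomes with family-clustered sandwich standard errors,
    Nagelkerke delta R-squared, and false discovery rate correction. A
    liability-threshold trio simulator with Mendelian transmission provides
    fully synthetic cohorts for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    sandwich,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
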