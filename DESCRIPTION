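Package: pcdgrs
Title: Genetic Risk Score Construction and GRS-Stratified Phenotype
    Clustering for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an unweighted allele-count genetic risk score (GRS)
    from a curated SNP panel (minor-allele-frequency, imputation-quality
    and linkage-disequilibrium filters; Hardy-Weinberg and call-rate
    genotype QC), stratifies patients by two-step cluster analysis of
    GRS, lung function and age of onset with log-likelihood distance and
    BIC-based selection of the number of clusters, identifies
    GRS-extreme clusters by Tukey HSD contrasts against healthy
    controls, and tests per-SNP allele-frequency differences between the
    extreme groups with fixed-effect meta-analysis across cohorts.
    Includes a synthetic multi-cohort case-control simulator so the
    whole pipeline is testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
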