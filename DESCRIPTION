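Package: apoeprs
Title: APOE-Stratified Polygenic Risk Score Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Kronos", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end polygenic risk score (PRS) pipeline for
    Alzheimer's-style case-control data with APOE stratification: a
    synthetic cohort generator (block-LD haplotypes, imputation-style
    genotype probabilities, an APOE locus with E2/E3/E4 alleles, and a
    liability/logistic disease model), Oxford GEN/SAMPLE input-output,
    imputation QC (Info score and minor allele frequency filters),
    hard-calling, per-SNP logistic association with covariates, principal
    components, p-value-ordered greedy LD pruning, threshold-selected
    allele-aligned scoring with optional APOE-region exclusion, APOE
    genotype stratification, ROC/AUC evaluation with DeLong confidence
    intervals, risk/alternative allele-burden contingency comparisons, and
    a simulation-based adjustment for discovery/test sample overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
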