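Package: shgm
Title: Sum of High-Risk Gene Mutation Scoring for Adrenocortical Tumor Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mutation-burden scoring on a nine-gene targeted panel
    (TP53, CTNNB1, ARMC5, PRKAR1A, ZNRF3, RB1, APC, MEN1, RPL22) used to
    assist the differential diagnosis of adrenocortical carcinoma (ACC)
    versus benign adenoma (ACA). Starting from annotated variant calls, the
    package filters variants for biological significance (effect class and
    population allele frequency), collapses them into a gene-by-sample
    mutation matrix stored as a SummarizedExperiment, compares per-gene
    mutation rates between groups with two-sided exact tests
    (minimum-likelihood rule), selects high-risk genes, computes the
    per-sample sum of mutated high-risk genes (SHGM), and evaluates SHGM
    thresholds as a diagnostic rule (sensitivity, specificity, PPV, NPV).
    A calibrated synthetic-cohort generator with a quiet/active mixture
    model supports testing and power exploration without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, SomaticMutation, Classification, TargetedResequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
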