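Package: proteoPanel
Title: Multi-Stage Proteomic Biomarker Panel Discovery and Co-Expression
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for aptamer-based case-control
    proteomics: quality control and normalization of relative-fluorescence-unit
    expression matrices (log2 transform, Z-score standardization, covariate
    residualization, empirical-Bayes batch adjustment, principal-component
    confounder scans); simulated-annealing protein ranking with nested
    random-forest panel classifiers evaluated by permutation-tested ROC AUC
    across tissue modalities; single-score signature compression (mean-Z and
    SVD eigengene) with clinical-outcome association; per-protein GLM
    differential-regulation scans with Benjamini-Hochberg control;
    hypergeometric over-representation analysis of GMT gene sets; weighted
    co-expression module detection via topological overlap with module
    eigengenes, hub proteins and module-trait regression; and composite
    severity scoring with stratified classifier evaluation. Includes a
    synthetic multi-cohort, multi-modality study generator with planted
    case-associated proteins, severity-coupled effects, correlated
    co-expression blocks and batch structure, so every stage is testable
    without access to clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, randomForest, sva
Suggests: testthat (>= 3.0.0), pROC, mclust, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
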