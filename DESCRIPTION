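Package: fragstack
Title: Stacked-Ensemble Classification of Plasma cfDNA Fragmentomics Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts three families of whole-genome cfDNA fragmentomics
    features from aligned fragment data -- per-bin copy-number log2 ratios
    against a panel of normals (CNV), per-arm fragment size distributions
    (FSD), and CpG 5' end-motif ratios in Alu repeats as a methylation proxy
    (FRAGMA) -- and combines them in a stacked ensemble of six learner
    families with cross-validated scoring, a specificity-anchored decision
    cutoff, and ROC/confusion-matrix evaluation with exact confidence
    intervals. Ships a synthetic cohort simulator with a tumor-fraction dial
    so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    glmnet,
    ranger,
    nnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Classification, CopyNumberVariation, Sequencing, Epigenetics
RoxygenNote: 7.3.3
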