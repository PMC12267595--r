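Package: il2kit
Title: Predicting, Designing and Scanning Interleukin-2 Inducing Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for sequence-based prediction of interleukin-2 (IL-2)
    inducing peptides. Provides labeled peptide-set containers built on
    Biostrings, dataset curation and stratified train/test splitting,
    composition-based peptide descriptors (amino-acid and dipeptide
    composition, composition-transition-distribution, physicochemical class
    composition, residue-repeat and distance-distribution indices, terminal
    binary profiles), discriminative motif mining over plain and degenerate
    residue-class alphabets, classical machine-learning classifiers tuned by
    grid-search cross-validation with rank-based AUC, feature selection,
    a hybrid scoring rule combining model probability with motif evidence,
    dataset characterization analyses, and workflows for peptide prediction,
    single-residue mutant design, protein window scanning and motif scanning.
    Includes a synthetic peptide-set generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rpart,
    ranger,
    nnet,
    class,
    e1071,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
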