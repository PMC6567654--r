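Package: cpf1design
Title: Convolutional Classifiers and Guide RNA Library Design for CRISPR-Cpf1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing CRISPR-Cpf1 (Cas12a) guide RNA libraries
    from DNA sequence alone. Provides one-hot encoders for matched 27-nt
    TTTN-protospacer targets (order 1-3 k-mer schemes) and for guide/target
    mismatch pairs (12 mismatch types x 27 positions), two small
    convolutional network classifiers for on-target activity and off-target
    specificity trained by mini-batch gradient descent with momentum, an
    evaluation harness (extreme-split labelling, external cross-validation,
    ROC/AUC, F1, Spearman correlation, cutoff grids), permutation importance
    over the flatten layer with receptive-field projection back onto the
    input matrix, a TTTN-N23 candidate scan with GC and polyT filtering,
    mismatch-aware off-target enumeration and specificity scoring, and
    synthetic data generators with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    randomForest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
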