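Package: AmyloHex
Title: Amyloidogenic Hexapeptide Classification by Simplified
    Steric-Zipper Threading and Sequence-Based Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of six-residue peptides (hexapeptides) as
    amyloidogenic or not. Implements energy-threshold labeling over a
    simplified 54-template steric-zipper enumeration (two five-strand
    beta-sheets, rigid-body shifts of 0-8 Angstrom along the chains and
    6-11 Angstrom across the sheets, with a pluggable per-chain energy
    adapter), a from-scratch Alternating Decision Tree learner over
    position-residue predicates with rule export, categorical Naive Bayes
    and one-hidden-layer perceptron baselines, confusion/ROC/AUC
    evaluation, a 10-run 66/34 resampling protocol with the corrected
    resampled paired t-test and win/draw/loss tabulation, and seeded
    synthetic generators for hexapeptide datasets and paired energy
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
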