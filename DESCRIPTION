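Package: medner
Title: Ensemble Named-Entity Recognition of Medication Information in
    Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes medication-related fields (drug name, dosage,
    mode, frequency, duration, reason) in discharge-summary-like
    clinical notes.  Implements a BIO sequence-labeling data model with
    an i2b2-2009-style annotation dialect, a lexicon-and-pattern rule
    tagger, a one-vs-one polynomial-kernel SVM tagger and a linear-chain
    conditional random field over six token feature families, three
    ensemble voting strategies combining the three systems, chunk-level
    micro-averaged precision/recall/F evaluation, k-fold
    cross-validation orchestration, an approximate-randomization
    significance test, and a seeded synthetic-corpus generator with a
    label corrupter for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
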