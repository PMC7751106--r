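Package: memvote
Title: Membrane Protein Detection by Evidential Ensemble Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects membrane proteins from amino-acid sequences and
    PSI-BLAST profile matrices. Implements five fixed-length protein
    encodings (amino acid composition, dipeptide composition, pseudo
    amino acid composition, split amino acid composition, and the
    pseudo position-specific scoring matrix descriptor), a
    lambda-parameterized bank of base classifiers centred on the
    evidence-theoretic k-nearest-neighbour rule, all-voting and
    mRMR-driven selective-voting ensembles, weighted-vote integration
    with external transmembrane-topology calls, and a leave-one-out /
    k-fold evaluation harness with sensitivity, specificity, accuracy,
    Matthews correlation and ROC/AUC. A deterministic synthetic-data
    generator provides sequences, profiles and topology calls with a
    controllable class signal so the full pipeline can be exercised
    without external searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    class,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
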