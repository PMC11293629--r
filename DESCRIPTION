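Package: pcmer
Title: Physicochemical k-mer Profiles for Alignment-Free Sequence Comparison and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Alignment-free feature extraction for DNA/RNA sequences based on
    three physicochemical binary re-alphabetings (purine/pyrimidine,
    amino/keto, weak/strong) profiled by a one-dimensional chaos-game
    recurrence into three 2^k count vectors, replacing the 4^k cells of a
    classical k-mer (FCGR) spectrum with 3*2^k grouped counts. Includes the
    classical four-letter FCGR baseline and the exact group-collapse relation
    between the two encodings, Manhattan-distance sequence comparison with
    retrieval AUC and distance-matrix correlation, a supervised classification
    harness (eight basic classifiers, stratified cross-validation, four
    metrics), a Markov-chain synthetic sequence generator with mutation and
    divergence series, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    seqinr,
    glmnet,
    rpart,
    e1071,
    MASS,
    nnet,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
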