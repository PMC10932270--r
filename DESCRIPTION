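Package: modsite
Title: Multi-Scale k-mer Transformer Prediction of RNA Modification Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts post-transcriptional RNA modification sites (m1A, m6A,
    pseudouridine) from fixed-width sequence windows with a biological
    language-model approach: overlapping k-mer tokenization at scales k = 3..6,
    a bidirectional transformer encoder, a learned sigmoid fusion gate that
    blends two k-mer scales, and fast-gradient-method (FGM) adversarial
    fine-tuning.  Ships a planted-motif synthetic benchmark generator,
    stratified cross-validation and cross-species evaluation (Sn, Sp, Acc,
    MCC, ROC AUC), and attention-based interpretation tools that map token
    attention to nucleotide positions, harvest position frequency matrices,
    export MEME minimal motifs and scan for over-represented wildcard
    substrate patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
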