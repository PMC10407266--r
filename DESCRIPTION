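Package: attnms1
Title: Attention-Based Prediction of Peptide MS1 Intensity from Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-to-scalar deep learning for peptide-level MS1 response.
    Implements a bidirectional-GRU encoder-decoder with an additive attention
    mechanism that predicts peptide MS1 intensity from amino acid sequence
    alone, together with the supporting workflow: parsing of MaxQuant
    peptide-level output and SDRF metadata, quality/replication/variation
    filtering and enzyme-based segmentation, intensity transformation and
    sequence encoding, attention-weight interpretation against AAindex1
    physicochemical indices, synthetic proof-of-concept data generators with
    known per-symbol contributions, and random-forest / ridge baselines with
    a 5-fold cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    glmnet,
    ranger,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
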