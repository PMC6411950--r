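Package: lemp
Title: Ensemble Prediction of Lysine Malonylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lysine malonylation (Kmal) sites in protein sequences by
    combining a recurrent neural network trained on learned residue embeddings
    (LSTM_WE) with a random forest trained on an enhanced amino-acid-composition
    (EAAC) sliding-window encoding (RF_EAAC), integrated through a logistic
    model (LEMP). Includes the full dataset-construction pipeline
    (high-confidence site filtering, greedy identity-based redundancy
    reduction, aligned-positive exclusion, conflicting 7-mer removal,
    gap-padded 31-residue window extraction, protein-grouped splits and
    cross-validation), several peptide feature encodings (EAAC, AAC, AAindex,
    one-hot, BLOSUM62, binary, CKSAAP, Z-scales), evaluation measures
    (accuracy, sensitivity, specificity, MCC, ROC/AUC and partial AUC at low
    false-positive rate), interpretation analyses (two-sample-logo residue
    enrichment, information-gain feature ranking, hierarchical clustering of
    learned embeddings), and a seeded synthetic-proteome generator with
    plantable sequence motifs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    ape,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
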