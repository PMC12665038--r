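Package: etnet
Title: Enhancer-Enhancer Interaction Prediction from Paired DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts physical interactions between pairs of enhancer elements
    directly from DNA sequence. Builds labelled enhancer-enhancer interaction
    datasets from chromatin-interaction loops (BEDPE) and enhancer annotations
    (BED), with three negative-sampling strategies and leakage-controlled data
    splits; trains a two-branch convolutional + Transformer-encoder classifier
    on one-hot encoded sequence windows; supports selective fine-tuning for
    cross-context transfer with a frozen encoder; evaluates with ROC/PR metrics
    and the paired DeLong test; and interprets trained models via dinucleotide-
    shuffle perturbation, greedy functional-region search, super-additivity
    statistics, attribution-derived motif matching against JASPAR/MEME motif
    databases, and in-silico variant effect scores. A synthetic-fixture
    generator produces toy genomes with planted motif pairs so the full
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
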