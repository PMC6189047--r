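Package: kmergru
Title: Transcription Factor Binding Site Prediction with k-mer Embeddings
    and Bidirectional Gated Recurrent Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether short DNA sequences are transcription factor
    binding regions. Sequences are split into overlapping k-mers with a
    configurable length and stride, k-mers are embedded as dense vectors
    learned from co-occurrence statistics (a word2vec-style skip-gram/CBOW
    trainer with negative sampling, written in C++), and the embedded k-mer
    sequence is classified by a bidirectional gated recurrent unit network
    trained by minimising the Bernoulli negative log-likelihood. Includes a
    synthetic ChIP-seq-style data generator (motif-bearing positives and
    composition-matched negatives), evaluation with ROC AUC and average
    precision, a hyper-parameter grid search, an embedding-strategy
    ablation, and sensitivity sweeps over k, stride and embedding dimension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
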