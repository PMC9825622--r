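Package: declm
Title: Hybrid Chemical Language Models for Activity-Focused De Novo Molecular Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline for activity-focused de novo molecular
    design with hybrid chemical language models. Provides a generative
    recurrent (LSTM) SMILES language model with temperature and nucleus
    (top-p) sampling, ELECTRA-style replaced-token pretraining, an ordinal
    three-class bioactivity classifier used as a deep voting ensemble, and
    the supporting library analytics: generation quality metrics (validity,
    uniqueness, novelty), Morgan-fingerprint Tanimoto similarity,
    Bemis-Murcko atom and graph scaffold novelty, Frechet distance between
    molecule-set embeddings, reciprocal-rank-fusion virtual screening, and
    Hill-model dose-response Kd fitting. Synthetic corpus generators make
    every component testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
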