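Package: qadiscourse
Title: Topic and Sentiment Discourse Analysis for Community Q&A Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing public discourse on
    community question-and-answer platforms. Questions are categorised by
    Latent Dirichlet Allocation (collapsed Gibbs sampling) with
    coherence-guided model selection, a configurable merge of raw topics
    into interpretable labels, and an embedding space (positive pointwise
    mutual information factored by singular value decomposition) in which
    each merged topic is represented by the centroid of its document
    vectors. Answers are classified as positive or negative by chunked
    scoring with a bagging ensemble of pluggable sentiment scorers, with a
    deterministic lexicon scorer as the reference backend.
    Question-answer sentiment pairs are cross-tabulated per topic, and
    monthly sentiment series are summarised by majority crossovers and
    dominance streaks. A synthetic corpus generator with planted topic,
    sentiment, and temporal structure makes every stage testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
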