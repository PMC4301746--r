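Package: bioranker
Title: Neural Relevance Ranking and Query Assistance for Biological Record Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained search library for multi-attribute biological
    database records: a positional inverted index with a TF-IDF vector-space
    baseline ranker, query assistance (Damerau-Levenshtein spelling
    suggestions, ontology-synonym expansion, related-entry suggestion), an
    eleven-dimensional per-hit relevance feature extractor, a feed-forward
    neural network ranker (11-16-8-1, sigmoid) trained by backpropagation
    from five-class graded relevance feedback, evidence-sorted
    gene-annotation link resolution, a graded-relevance evaluation harness
    (per-class score distributions and Mann-Whitney AUC separation), seeded
    synthetic corpus generators with planted class-graded relevance signal,
    and a command-line interface with CSV/XLSX result export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
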