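Package: mirmine
Title: Mining miRNA Mentions and Concept Co-Occurrences in PubMed Citation Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses MEDLINE/PubMed tagged-format citation exports, extracts
    miRNA mentions from titles and abstracts and normalizes them to
    family-level identifiers (miR-N), tags curated concept dictionaries
    (cell types, cytokines, pathological processes), and counts
    per-article-deduplicated miRNA publication counts and miRNA-by-term
    co-occurrence matrices across disease corpora. Ranks the most-published
    miRNA families per corpus, scores cross-corpus breadth, and renders
    publication-trend, ranking, donut and heatmap reports. Ships a seedable
    synthetic-corpus generator that emits exact ground-truth tables, serving
    as an independent oracle for the counting engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
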