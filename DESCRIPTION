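Package: webiq
Title: Quantitative Quality Metrics for Web-Based Health Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates a university student health center (SHC) website,
    gathers keyword-anchored textual content from it, and computes eight
    quantitative information-quality metrics: Flesch Reading Ease,
    Flesch-Kincaid Grade Level, keyword prevalence, keyword coverage,
    objectivity, polarity, navigation distance (minimum clicks by
    breadth-first search), per-page timeliness (Last-Modified), and cosine
    similarity against an ideal reference document. Ships a deterministic
    synthetic-website fixture generator so the whole pipeline runs and is
    testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    xml2
Suggests:
    curl,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
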