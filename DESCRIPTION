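Package: nutriminer
Title: Information Extraction for Diet-Microbiome Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end information-extraction toolkit for the
    diet-microbiome literature: reading and writing brat-style standoff
    corpora with nested and discontinuous entity mentions, relation
    triggers and certainty attributes; span-based named-entity and
    trigger recognition with levitated-marker packing; trigger-aware
    relation classification and factuality (certainty) classification;
    strict and relaxed evaluation with bootstrap confidence intervals
    and inter-annotator agreement; a deterministic synthetic corpus
    generator with an exact ground-truth ledger; and an offline
    harness for zero- and one-shot relation extraction with
    chat-completion models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
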