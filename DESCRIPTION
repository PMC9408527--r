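Package: narrex
Title: Rule-Based Information Extraction from Patient-Experience Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting structured answers from collections of short
    free-text patient-experience narratives. Provides corpus reading with
    period-based sentence segmentation and word tokenization, frequency-list
    construction with a minimum-length function-word filter, a semantic-syntactic
    lexicon of non-exclusive word groups, a lexical-syntactic frame matching
    engine with adjacent (++) and within-sentence (+) binding operators, binary
    classification of texts against dichotomous queries, and an evaluation
    protocol benchmarking automatic classifications against two human readers
    (inter-rater agreement, 0/0.5/1 consensus ranks, Spearman rank correlation).
    A seeded synthetic-corpus generator with planted phrases and simulated
    readers makes the whole pipeline testable without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
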