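Package: symtalk
Title: Rule-Based Detection of Symptom Talk in Clinical Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building, curating and evaluating keyword libraries
    that detect turn-level "symptom talk" in transcribed clinical
    conversations, grounded in the PRO-CTCAE symptom framework. Provides a
    versioned keyword-lexicon data model with exclusion patterns and
    diff/filter machinery, transcript readers with span-preserving
    tokenization, a turn-level matcher with keyword-in-context concordance
    views, gold-standard construction from multi-coder 0-3 relevance scores
    (including a manually overridden PRO-CTCAE-focused standard) with Cohen
    and Fleiss inter-rater kappa, confusion-matrix evaluation with the five
    standard metrics and stratified reporting, seeded misclassification
    sampling for qualitative review, n-gram candidate mining for iterative
    lexicon curation, and a synthetic-conversation generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
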