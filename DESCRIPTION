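Package: medikb
Title: Construction and Evaluation of Medication-Indication Knowledgebases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build, evaluate, and release medication-indication
    knowledgebases in the style of MEDI-2: harmonize medications to
    ingredient-level RxNorm identifiers, extract indication concepts from
    structured relationship tables and sectioned free-text drug articles
    (dictionary-based concept indexing with negation detection and a
    semantic-type filter), map UMLS concepts to ICD-9-CM/ICD-10-CM with a
    SNOMED-CT fallback, aggregate assertions with per-resource provenance,
    select a high-precision subset, and estimate weighted precision from
    manual-review counts. Ships a deterministic synthetic-fixture generator
    so the full pipeline is testable offline without licensed terminologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
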