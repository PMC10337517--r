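Package: fhlex
Title: Family History Lexicon Construction and Rule-Based Extraction from
    Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and manages a normalized family-history (FH) semantic
    lexicon (surface variants mapped to UMLS concept unique identifiers and
    optional SNOMED-CT codes, restricted to disorder/finding semantic types)
    and uses it in a rule-based system that extracts family members,
    observations, living status, and ages from clinical note text, links
    them into FH relations by clause co-occurrence and bounded cross-sentence
    coreference, and scores the output with challenge-style precision,
    recall, and F1 as well as lexicon-coverage recall at the variant and
    concept level. Includes a corpus-driven lexicon construction pipeline
    with pluggable mention-source and normalizer adapters, a frequency
    thresholded manual-curation queue, and a synthetic note generator with
    self-annotating gold standards so every stage is testable without
    access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
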