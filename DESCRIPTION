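Package: vmodel
Title: Problem-Action Timelines for Narrative Clinical Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models pre-annotated narrative clinical events as v-shaped
    Problem/Action structures anchored to temporal anchor points (TAPs) on a
    dynamically scaled timeline. Parses non-explicit temporal expressions
    (two-digit years, fuzzy modifiers, semi-intervals, relative offsets,
    proximity hints) into granularity-aware calendar intervals, performs
    qualitative and quantitative temporal reasoning over them, renders
    timelines to deterministic SVG, and mines context-block patterns across
    patient cohorts into include/exclude phenotype candidate rules. Includes
    a synthetic cohort generator and a command-line interface.
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
    withr,
    xml2
Config/testthat/edition: 3
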