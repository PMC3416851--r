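Package: tagforge
Title: Design and Validation of Error-Correcting DNA Sequence Tags
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with DNA sequence identification tags
    (barcodes, indexes) used to multiplex samples on massively parallel
    sequencing platforms. Validates existing tag sets for conformance to
    the Levenshtein (edit) or Hamming distance metric, designs maximal
    sets of edit-distance tags robust to insertion, deletion, and
    substitution errors with a summary-vector accelerated greedy lexicode
    construction, integrates tags into PCR primers and sequencing
    adapters with junction trimming and secondary-structure screening,
    and quantifies error-correction capacity with closed-form and
    Monte-Carlo error models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
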