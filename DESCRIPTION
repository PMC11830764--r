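Package: schemarsa
Title: Searchlight Representational Similarity Analysis of History-Dependent Event Codes
Version: 1.0.0
Authors@R:
    person("Sam", "Verhagen", email = "sam.verhagen@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting history-dependent multivoxel codes during
    structured event sequences with leave-one-event-out template
    representational similarity analysis (RSA). Implements schema, path,
    current-ritual, rotated (anticorrelated) preceding-ritual and
    non-rotated preceding/upcoming contrasts over cubic searchlights,
    group-level one-tailed tests with false-discovery-rate correction,
    conjunction and disjunction region logic, JZS Bayes factors, and a
    within-participant permutation test linking per-event neural code
    strength to subsequent memory. Ships a synthetic multivoxel pattern
    generator that plants each code with known amplitude so the whole
    pipeline is testable end to end, plus NIfTI/TSV/YAML input-output and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
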