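Package: fitassay
Title: Fitness-Curve Analysis and QTL Mapping for Liquid Feeding Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Quantifies treatment effects on Caenorhabditis elegans
    populations from 96-well OD600 feeding ("fitness") curves. Provides
    start-OD normalization, the 2x2 curve-signature chi-square test, endpoint
    and slope t-tests, genome-wide single-marker QTL scans over recombinant
    inbred lines with permutation-based significance thresholds, chi-square
    classification of lines against parental references, worm-number
    sensitivity analysis, and a synthetic-data generator that reproduces the
    statistical structure of the assay for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
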