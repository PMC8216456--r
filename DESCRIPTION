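Package: covscreen
Title: Covariation-Based Screening for Conserved RNA Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for detecting evolutionarily conserved RNA secondary
    structure in multiple sequence alignments. Scores all column pairs with
    a G-test covariation statistic, calibrates per-pair E-values against a
    column-permutation null, folds the consensus under covariation
    constraints with a weighted Nussinov/CYK dynamic program, and classifies
    alignments as structural-RNA candidates using stem-aware significance
    criteria with Fisher's-method P-value aggregation. Also includes H/ACA
    box snoRNA motif detection, guide-target pseudouridylation-site search
    with wobble pairing and shuffle-based false positive rates, region
    windowing utilities for genome screens, and seeded simulators of
    alignments with planted compensatory base-pair substitutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
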