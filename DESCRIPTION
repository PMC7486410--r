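Package: cahub
Title: Population Calcium-Imaging Analysis of Network Bursts, Assemblies
    and Hub Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for binary onset rasters from population
    calcium imaging. Detects network bursts (giant depolarizing
    potentials) in developing hippocampal slices with circular-shift
    surrogate thresholds, tests single-cell stimulation effects on burst
    frequency and timing, classifies locomotion- and synchronous-calcium-
    event-modulated cells in vivo, extracts ICA-based cell assemblies and
    their activities, infers directed functional-connectivity graphs from
    pairwise spike-lag distributions with hub classification, and provides
    matched-subsampling bootstrap and exact contingency statistics for
    tagged-cell group comparisons. Includes calibrated synthetic-session
    generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
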