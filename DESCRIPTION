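Package: pseudorank
Title: Profile-Based Pseudo Protein Sequences and Rank Aggregation for
    Remote Homology Detection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for protein remote homology detection by score fusion.
    Builds per-position amino-acid frequency profiles from multiple sequence
    alignments or PSI-BLAST ASCII position-specific scoring matrices,
    converts them into consensus ("pseudo") protein sequences, combines
    ranking lists from several homology-search predictors by min-max
    normalized linear weighted rank aggregation, and evaluates rankings with
    truncated ROC (ROC1/ROC50) statistics under a jackknife protocol on
    SCOP-style family/superfamily benchmarks. Includes parsers for BLAST
    tabular, HMMER tblout and HHblits HHR output, an exhaustive simplex grid
    search for aggregation weights, and seeded synthetic-benchmark
    generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
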