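Package: orthocircuit
Title: Orthogonality Screening and Logic-Circuit Scoring for
    Cas-Responsive Translational Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for panels of Cas-responsive
    translational switches characterized by flow cytometry and imaging:
    event-level gating (debris, edge and mock-derived reference-positive
    gates), median-ratio normalization of reporter against reference
    fluorescence, construction of trigger-by-switch fold-change matrices,
    orthogonality screening by minimum pairwise cosine distance of centered
    fold-change profiles with exhaustive and optimized max-min best-subset
    search, and truth-table scoring of translational logic circuits by net
    fold-change and vector proximity angle. Includes a synthetic-data
    generator with planted multiplicative effects so every stage is testable
    end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
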