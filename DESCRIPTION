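Package: fingermap
Title: BAC Fingerprint Physical Map Construction and Anchoring
Version: 0.9.0
Authors@R:
    person("fingermap", "maintainers", email = "fingermap@example.org", role = c("aut", "cre"))
Description: Tools for building and anchoring BAC-clone physical maps from
    high-information-content restriction fingerprints (HICF). Implements
    Sulston-score overlap probabilities, overlap-net construction with
    questionable-clone and questionable-overlap removal, adaptive clustering
    into linear contigs with coordinate layouts, minimum tiling path (MTP)
    selection with overlap reinforcement, three-dimensional MTP pool design,
    PCR and microarray pool-screen deconvolution with confidence tiers,
    deletion-bin mapping with coverage-corrected bin sizes, synteny-rank
    contig ordering, supercontig elongation, gene-island statistics, and
    map-level summaries (N50/L50, coverage, marker density). A synthetic-data
    module simulates chromosome arms, clone libraries, noisy fingerprints,
    planted markers and pool-screening signals with full ground truth, at the
    statistical regime of a wheat chromosome-arm mapping project.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
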