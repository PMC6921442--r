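Package: ehralign
Title: Global and Local Alignment of Daily Diagnosis-Event Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns patient medical records viewed as temporal sequences of
    set-valued daily events (the diagnosis codes recorded on one date). Provides
    four dynamic-programming aligners -- dynamic time warping (DTW) and
    Needleman-Wunsch (NWA) for global alignment, and their local counterparts
    DTWL and Smith-Waterman (SWA) -- under a Jaccard-based scoring system that
    rewards matching daily events, penalizes mismatches and gaps, and
    score-penalizes the extra events inserted by warping. Includes a synthetic
    medical-record generator (delete/update/switch operations on daily events
    and event blocks, with full provenance), ground-truth reference alignments
    derived from that provenance, and a benchmark harness producing normalized
    similarity scores and seed-coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
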