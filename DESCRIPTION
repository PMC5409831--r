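Package: prc2mem
Title: Stochastic Simulation of Transcription-Antagonized Polycomb Chromatin
    States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact (direct-method) stochastic simulation of a PRC2 target-gene
    chromatin domain in which transcription antagonizes H3K27 methylation.
    Tracks per-histone K27 methylation (me0-me3), transcription-coupled
    demethylation and nucleosome exchange, allosteric PRC2 feedback from
    neighboring me2/me3 marks, and random histone dilution at DNA replication.
    Includes the non-processive main model and its two-state, processive, and
    promoter-switching (bursty transcription) variants; a two-stage birth-death
    model of a noisy trans-acting regulator; bistability and first-passage-time
    analysis of simulated trajectories; and a SILAC-style old/new-histone
    labeling and fitting harness with a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
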