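Package: swnet
Title: Small-World Analysis of EEG Beta-Band Lagged-Coherence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for resting-state EEG functional
    connectivity in sensorimotor cortical networks. Generates synthetic cohorts
    of band-limited, lag-coupled region-of-interest current-density time series
    with subject metadata; preprocesses raw multichannel recordings
    (anti-aliased downsampling, zero-phase FIR band-pass filtering, automated
    bad-channel detection, fixed-length epoching, amplitude-based epoch
    rejection, channel interpolation, common-average re-referencing); estimates
    lagged linear coherence in a configurable frequency band; computes
    surrogate-normalized weighted clustering, characteristic path length and
    small-world indices over motor and sensory Brodmann-area networks; and runs
    the group-level mixed-design analysis of variance with Bonferroni post-hoc
    contrasts and nonparametric demographic tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
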