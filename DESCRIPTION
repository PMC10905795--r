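Package: eegnetvar
Title: Large-Timescale Variability of EEG Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the day-scale variability of EEG
    functional brain networks in disorders of consciousness. From repeated
    resting-state recordings (five sessions per patient at two-hour
    intervals) it computes weighted phase lag index (wPLI) connectivity,
    weighted graph metrics (characteristic path length, clustering
    coefficient, betweenness centrality), and session-to-session
    variability statistics (normalized mutual information between network
    module partitions, global explained variance, coefficients of
    variation), followed by nonparametric group contrasts and Kendall
    correlations with a behavioural consciousness score. Includes a
    synthetic-cohort generator of phase-coupled oscillatory sources with
    group-controlled between-session coupling variability, a deterministic
    preprocessing chain (zero-phase FIR filtering, epoching, statistical
    bad-channel and bad-epoch rejection, spherical-spline interpolation,
    common average reference), and BrainVision/EDF file I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
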