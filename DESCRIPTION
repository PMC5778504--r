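Package: bubbleFRET
Title: Simulation and Kinetic Analysis of Single-Molecule FRET
    Transcription-Bubble Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying conformational states and
    opening/closing kinetics of the transcription bubble in RNA
    polymerase-promoter complexes from alternating-laser-excitation
    (ALEX) single-molecule FRET time traces.  Includes a ground-truthed
    trajectory simulator (continuous-time Markov kinetics, photon shot
    noise, EMCCD gain, photobleaching), apparent FRET efficiency and
    stoichiometry computation with population histograms and Gaussian
    mixture summaries, algorithmic trace quality control and behavioural
    classification, variational-Bayes hidden Markov model segmentation
    with evidence-based model selection, and dwell-time
    exponential/bi-exponential kinetic fitting with bootstrap confidence
    intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
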