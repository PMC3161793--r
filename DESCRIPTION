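Package: avlocnet
Title: Bayesian-Network Modeling of Audiovisual Spatial Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven elicitation and evaluation of a generative model of
    audiovisual spatial perception. Simulates seeded behavioral datasets from a
    ventriloquism-style localization protocol (acoustic and visual tasks,
    unisensory and bisensory presentations), extracts decision times and
    normalized localizations from pointer trajectories, discretizes every
    variable with fixed histogram binnings, learns the dependence structure by
    normalized mutual information against null-calibrated thresholds with
    conditional-mutual-information pruning and d-separation based edge
    orientation (including context-specific-independence multinets), fits the
    resulting factorization by maximum likelihood with Gaussian percept and
    log-normal decision-time conditionals, and evaluates maximum-a-posteriori
    predictions by leave-one-subject-out cross-validation with
    coefficient-of-determination summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
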