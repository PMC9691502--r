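Package: dynthresh
Title: Dynamic-Threshold Spike-Train Models with Correlated Interval Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spike trains generated by a
    non-resetting dynamic (adaptive) spike-threshold neuron with a
    stochastic firing threshold. Generates spike trains whose
    interspike-interval (ISI) serial correlation coefficients (SCCs)
    follow prescribed Type I (monotone negative), Type II (alternating
    damped) or Type III (degenerate) patterns by colouring the threshold
    noise with a first-order autoregressive process. Provides the
    closed-form forward map from the threshold-noise autocorrelation
    function to the ISI SCCs, its inverse, blockwise SCC estimation,
    partial autocorrelation by Durbin's recursion, ISI and joint-ISI
    histograms, low-frequency spectral checks, and routines for matching
    model parameters to target spike-train statistics, including firing
    locked to an electric-organ-discharge (EOD) cycle grid as in P-type
    electrosensory afferents of weakly electric fish.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
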