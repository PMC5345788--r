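Package: minis
Title: Simulation and Kinetic Analysis of Miniature Inhibitory Postsynaptic Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of miniature inhibitory
    postsynaptic currents (mIPSCs) recorded under whole-cell voltage clamp,
    together with a synthetic trace generator for closed-loop validation.
    Implements threshold-based event detection with amplitude, duration and
    rise-time acceptance rules, per-event kinetics (10-90% rise time, charge
    transfer, 70% decay time), rise-midpoint-aligned event averaging,
    mono- and bi-exponential decay fitting with extra-sum-of-squares F-test
    model selection and the weighted decay time constant tau_w, cohort-level
    statistics (t tests, one-way ANOVA with Newman-Keuls post hoc tests,
    percent-of-control normalization), and scoring of behavioural nociception
    assays (tail-flick maximum possible effect, von Frey response frequencies,
    censored rotarod latencies) with matching non-parametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
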