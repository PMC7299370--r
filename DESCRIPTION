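Package: ampanoise
Title: Ensemble Noise and Kinetic Analysis of AMPA Receptor Patch-Clamp Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for macroscopic agonist-evoked currents recorded
    from excised membrane patches: non-stationary fluctuation analysis
    (pairwise ensemble variance, parabolic variance-mean fitting, weighted
    single-channel conductance and peak open probability), bi-exponential
    desensitization kinetics with weighted time constants, two-pulse recovery
    from desensitization, and rectification-index computation from
    current-voltage families. Includes a stochastic sweep simulator with
    binomial channel gating whose presets encode AMPA-receptor/TARP
    stoichiometry conditions, used to validate estimator recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
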