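Package: rrocr
Title: Chaotic Resonance Control of Chaos-Chaos Intermittency by
    Reduced-Region-of-Orbit Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a one-dimensional discrete map of
    frontal-cortex neural activity built from competing excitatory and
    inhibitory tanh nonlinearities, in which chaos-chaos intermittency
    (CCI) between positive- and negative-activity attractor regions models
    aberrant neural fluctuation.  Implements the "reduced region of orbit"
    (RRO) Gaussian-windowed feedback controller and a weak periodic
    reference stimulus, together with the analysis toolkit needed to
    characterise the controlled system: map extrema and the
    attractor-merging bifurcation condition, Lyapunov exponent estimation
    by the perturbation method, binarized delayed cross-correlation
    between orbit and stimulus, perturbation magnitude, and seeded
    multi-trial parameter sweeps (bifurcation diagrams, two-parameter
    Lyapunov grids, feedback-strength and measurement-noise sweeps)
    exported as self-describing TSV tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
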