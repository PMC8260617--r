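Package: megpursuit
Title: Simulation and Decoding of Covert and Overt Visual Pursuit from
    MEG-Like Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A simulation and analysis pipeline for asking whether covert
    attention and overt eye-movement control share neural substrates.
    Generates sinusoidal pursuit-target stimuli and task-dependent cortical
    current sources with distinct visual, attentional, and oculomotor
    subpopulations, projects them (together with ocular and cardiac artifact
    dipoles) to a synthetic MEG sensor array, estimates cortical and
    extra-brain source currents with a variational hierarchical Bayesian
    inverse, decodes target position and velocity with grouped
    automatic-relevance-determination sparse lagged regression, and
    quantifies cross-task generalization with normalized determination
    coefficients, permutation tests with false-discovery-rate control, and
    randomized-block ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
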