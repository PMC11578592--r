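Package: vigoureeg
Title: Saccadic Vigour, Preparatory EEG, and Mediation Analysis for
    Incentivised Eye-Movement Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for placebo-controlled incentivised-saccade
    experiments with concurrent EEG. Parses eye-position traces into saccades
    and computes residual peak velocity (vigour), saccadic reaction time, and
    distractor pull; extracts preparatory event-related potential window
    means (P3a, contingent negative variation) with amplitude and ocular
    artifact rejection; fits single-trial linear mixed-effects models with
    standardized coefficients; runs cluster-mass permutation tests over
    electrode-by-time grids and angle densities; and performs permutation-
    based mediation and mediated-moderation analysis. Includes a synthetic
    data generator that emulates the trial, eye-trace, and EEG structure of
    a two-session muscarinic-antagonist study so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
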