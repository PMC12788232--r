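Package: synergetics
Title: Muscle Synergy Extraction and Post-Activation Performance Statistics from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for muscle-synergy analysis of multi-channel surface
    electromyography (sEMG) recorded during explosive sport movements. Implements
    the standard envelope pipeline (zero-phase Butterworth band-pass, full-wave
    rectification, low-pass smoothing, amplitude normalization, time
    normalization to a fixed cycle grid, trial averaging), non-negative matrix
    factorization by multiplicative updates with variance-accounted-for (VAF)
    model-order selection, cross-condition synergy matching, temporal activation
    features, flight-time vertical-jump height, and a repeated-measures
    statistical layer (power/sample size via the noncentral F distribution,
    two-way within-subject ANOVA with partial eta squared, Friedman tests,
    corrected post-hoc comparisons, effect-size conversion). A seeded synthetic
    study generator with known ground-truth synergy structure makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'jumpstats.R'
    'pipeline.R'
    'preprocess.R'
    'synergetics-package.R'
    'synergy.R'
    'synthgen.R'
    'timing.R'
    'utils.R'
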