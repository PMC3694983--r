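Package: dmnconn
Title: Default-Mode Network Connectivity from Resting-State fMRI via Group ICA and Dual Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacological resting-state fMRI connectivity
    studies with a within-subject two-condition, two-segment design. Provides a
    synthetic multi-subject BOLD generator with planted spatial network nodes and
    condition-dependent correlation structure; temporal and spatial preprocessing
    (volume discard, linear detrend, cycle-based high-pass, Gaussian smoothing,
    segment extraction); temporally concatenated group spatial ICA (symmetric
    FastICA) with template-based default-mode-network component selection; dual
    regression to subject-level network maps; ROI definition by one-sample t-maps
    with FDR and Monte-Carlo-calibrated cluster-extent thresholds; nuisance-corrected
    pairwise Fisher-Z region connectivity; and 2x2 repeated-measures ANOVA with
    FDR-corrected post-hoc paired tests and brain-behavior correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
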