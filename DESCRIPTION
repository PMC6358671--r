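Package: painvar
Title: Within- and Between-Subject Variability of Stimulus-Evoked EEG Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decomposing the variability of
    stimulus-evoked electrophysiological responses into within-subject
    (trial-to-trial) and between-subject (trait) components. Provides a
    seeded generator of synthetic trial-structured EEG cohorts with
    controllable state and trait coupling between response features and
    perceptual ratings; epoch preprocessing (zero-phase band-pass
    filtering, baseline correction, re-referencing); single-trial
    time-frequency decomposition by windowed Fourier transform with
    percent-change baseline normalisation and separation of phase-locked
    from non-phase-locked power; extraction of the six canonical
    laser-evoked response features (N1, N2, P2, LEP, alpha-ERD,
    gamma-ERS); per-subject trial-wise correlation statistics with Fisher
    r-to-z group tests, between-subject correlations and false discovery
    rate control; point-by-point time-frequency statistic maps with
    cluster-based permutation testing; ROC analyses of stimulus
    discrimination and pain-sensitivity classification; mixed-design
    ANOVAs with partial eta squared effect sizes; and leave-one-out PCA
    plus random-forest prediction of individual pain sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
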