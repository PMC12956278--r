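Package: oppdyn
Title: Dynamics of Expectation Effects in Time-Resolved EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how stimulus expectation
    modulates category information in EEG during visual statistical
    learning. Provides a transitional-probability trial-sequence
    generator, a forward model that synthesizes continuous multichannel
    EEG with category-specific evoked patterns and expectation-dependent
    gain modulations, a preprocessing chain (zero-phase Butterworth
    filtering, resampling, blink removal by segment-wise SVD, denoising
    source separation, epoching, RMS-based trial rejection),
    time-resolved linear-SVM category decoding with SNR-based PCA
    feature selection and leave-one-trial-per-design-cell
    cross-validation, cluster-mass permutation statistics with
    family-wise error control over time, logarithmic learning-curve
    fits with a stabilization criterion, mixed-effects models of binned
    decoding accuracy, and reaction-time analyses with brain-behaviour
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
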