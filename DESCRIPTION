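Package: affectfuse
Title: EEG-Informed fMRI Analysis of Music-Induced Affect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of simultaneously recorded EEG and fMRI during
    music listening. Extracts prefrontal Laplacian band-power asymmetry and
    its Shannon-entropy dynamics from multichannel EEG, builds EEG-informed
    regressors on the fMRI time grid, fits a mass-univariate general linear
    model with a canonical double-gamma haemodynamic response function,
    controls the family-wise error rate by Bonferroni or max-statistic
    permutation, and separates affect-related from reporting-related voxels
    with an exclusion contrast. Includes a seeded synthetic-data generator
    emulating a three-trial-type music paradigm with valence-arousal
    circumplex targets, for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
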