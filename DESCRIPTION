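Package: arousalbias
Title: Phasic Arousal and Decision Bias: Pupillometry, Signal Detection,
    Drift-Diffusion and fMRI Pattern Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how phasic arousal, indexed by the task-evoked
    pupil response (TPR), modulates perceptual decision bias. Implements pupil
    preprocessing (blink interpolation, band-pass filtering, deconvolution-based
    artifact removal, percent-signal conversion), single-trial TPR quantification
    and a pupil general linear model with transient and sustained inputs,
    TPR-conditioned signal-detection metrics with balanced resampling and
    sequential polynomial regression, a stimulus-coded drift-diffusion model with
    an analytic first-passage-time likelihood (drift-criterion versus
    starting-point bias), fMRI response quantification and multivoxel pattern
    statistics (template correlation, choice logistic regression, hemispheric
    lateralization, searchlight classification, ROC predictive indices, brainstem
    partial correlations), and a synthetic-data generator with known ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
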