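Package: v1decode
Title: Decoding Visual Stimuli from Intra-V1 Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building stimulus-conditioned correlation networks within
    primary visual cortex (V1) and decoding observed stimuli from them. Implements
    a synthetic multi-subject block-design fMRI generator with retinotopic vertex
    maps and plantable condition-dependent network structure; nuisance regression,
    high-pass filtering and canonical/finite-impulse-response deconvolution GLMs;
    within-subject and common-response (inter-subject) correlation matrices with
    Fisher-z rectified edge features; linear support-vector-machine classification
    with t-test feature selection, leave-one-subject-out and two-direction
    cross-classification schemes, permutation tests and Fisher p-value combination;
    forward-model (Haufe) weight-map transformation with participant bootstrap,
    Kendall's W concordance, BCa intervals and visual-field quadrant sub-network
    summaries; a Gabor-pyramid simulation of gaze-driven V1 responses; and
    fixation heatmaps with mass-univariate mixed-model and bootstrap cluster-mass
    inference for eye-movement control analyses.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
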