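Package: strokesyn
Title: Multimodal Upper-Limb Stroke Assessment from sEMG and fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal assessment of upper-limb motor
    function after stroke during isometric elbow-flexion blocks. Extracts
    muscle-synergy indices from force-gated surface EMG (MCR-ALS decomposition
    with SIMPLISMA initialization, synergy stability index, closeness of the
    synergy vector and of the time profile), interhemispheric laterality
    indices from fNIRS (optical density, kurtosis-based wavelet motion-artifact
    correction, modified Beer-Lambert law, GLM beta maps), assumption-gated
    group statistics including a rank-based two-way Scheirer-Ray-Hare test,
    and an exhaustive four-predictor linear model of the Fugl-Meyer upper-limb
    score. Includes a synthetic cohort generator with known ground truth for
    validating every stage end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
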