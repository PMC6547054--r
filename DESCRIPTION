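Package: mpmmaps
Title: Quantitative MRI Map Creation from Multi-Parameter Mapping Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of quantitative MRI parameter maps (R1, effective
    transverse relaxation rate R2*, proton density PD and magnetisation
    transfer saturation) from multi-echo variable-flip-angle spoiled
    gradient-echo acquisitions. Implements joint log-linear R2* estimation
    across contrasts (ESTATICS), rational small-TR/small-angle map
    computation, transmit (B1+) and receive (B1-) bias-field correction
    including actual-flip-angle-imaging (AFI) B1 mapping, imperfect-spoiling
    correction, PD calibration, tissue-weighted (voxel-based quantification)
    smoothing, quality-assessment summaries, and a digital phantom simulator
    that generates the exact input format the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
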