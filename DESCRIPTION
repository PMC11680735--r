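Package: xepipe
Title: Quantitative Analysis of Hyperpolarized 129Xe Lung MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable processing pipeline for hyperpolarized xenon-129
    lung magnetic resonance imaging. Covers flip-angle calibration from free
    induction decay trains, gas and dissolved-phase spectral fitting (TE90,
    RBC:membrane ratio, T2*), threshold-based lung and airway segmentation,
    ventilation quantification with three ventilation-defect-percentage
    algorithms (mean-anchored thresholding, healthy-reference linear binning,
    hierarchical k-means) plus defect distribution index and gray-level
    run-length texture features, multi-b-value diffusion analysis (ADC mapping
    with log-linear, weighted and Bayesian fits, age-adjusted reference
    binning, stretched-exponential and cylinder morphometry models), and
    1-point Dixon gas-exchange decomposition with T2* and flip-angle
    corrections and generalized linear binning. A synthetic-phantom module
    generates ground-truth inputs for every stage, and readers/writers handle
    NIfTI, DICOM and an HDF5 raw-acquisition container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    rhdf5,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
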