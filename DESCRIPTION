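Package: ctperf
Title: CT Perfusion Deconvolution and Stroke Lesion Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end CT perfusion (CTP) analysis pipeline for acute
    ischemic stroke: vessel landmark refinement by grid-search ROI correction,
    rule-based and machine-learned validity checking of arterial input and
    venous output curves with warning logic, tissue-curve deconvolution by
    standard and block-circulant truncated singular value decomposition,
    voxelwise CBF/CBV/MTT/Tmax perfusion maps, and lesion volumetry (Volume F
    from rCBF < 30%, Volume T from Tmax > 6 s). Includes a digital perfusion
    phantom with gamma-variate bolus curves and known ground truth for
    validation, plus agreement and accuracy metrics (Lin's concordance
    correlation with bootstrap intervals, warning accuracy, two-proportion
    z-test, log-odds contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    nnet,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
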