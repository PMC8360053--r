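Package: spcnet
Title: Detection of Aggressive and Indolent Prostate Cancer on Bi-Parametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel detection of aggressive (Gleason pattern >= 4) and
    indolent (Gleason pattern 3) prostate cancer on bi-parametric MRI (T2-weighted
    and ADC volumes). Implements the full experimental pipeline around a branched
    multi-scale 2.5D convolutional network: a seeded synthetic phantom generator
    producing paired T2w/ADC volumes with histopathology-style ground truth and
    imperfect radiologist outlines; MRI preprocessing (in-plane resampling,
    prostate-centred cropping, histogram-landmark intensity standardization,
    in-gland z-scoring); fusion of Gleason-pattern maps and pathologist masks into
    three-class soft labels; class-weighted categorical cross-entropy training with
    patient-level cross-validation and fold-ensemble prediction; and pixel-, lesion-
    and patient-level evaluation with morphological lesion extraction, sextant
    negatives and ROC analysis, including a radiologist-comparison mode. The
    network forward/backward passes run on a compact BLAS-backed CPU engine
    included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
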