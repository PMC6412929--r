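Package: ecgscalo
Title: ECG Biometrics with Generalized Morse Wavelet Scalograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-lead electrocardiogram (ECG) biometrics.
    Denoises and segments raw ECG into fixed-length heartbeats, transforms
    beats into time-frequency scalograms using generalized Morse wavelets
    (continuous wavelet transform on a voices-per-octave scale grid),
    renders scalograms as fixed-size RGB images, classifies subjects with a
    small convolutional neural network trained with SGDM, RMSProp or Adam,
    and evaluates identification accuracy and one-against-all verification
    performance (sensitivity, specificity, ROC, equal error rate). Includes
    a multi-subject synthetic ECG generator with ground-truth R-peaks so the
    full pipeline is testable without clinical data, plus readers for
    delimited-text signals and PhysioNet-style WFDB records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
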