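Package: adipoCT
Title: Lower Radiation-Dose Limits for Automated CT Adipose Tissue Quantification
Version: 0.1.0
Authors@R: person("adipoCT", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to determine the lowest CT radiation dose at which automated
    quantification of subcutaneous (SAT) and visceral (VAT) adipose tissue
    remains acceptably accurate. Provides a synthetic abdominal CT phantom
    cohort generator with dose-dependent image noise and ground-truth fat
    masks, size-specific dose estimate (SSDE) dosimetry with slice-thickness
    normalisation, Hounsfield-window fat segmentation with classical
    denoising, fat-volume statistics, and a nonparametric (Mann-Whitney)
    testing ladder that derives an acceptable-accuracy threshold and the
    lower dose limit per fat compartment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
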