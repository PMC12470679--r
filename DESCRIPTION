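Package: liradsq
Title: Semi-Automated Quantification of Liver Lesions for LI-RADS v2018
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for arithmetic, software-assisted LI-RADS v2018 assessment of
    liver lesions on co-registered multi-phase contrast CT. Provides a synthetic
    four-phase CT phantom generator with known lesion ground truth, sphere-seeded
    region-growing lesion segmentation with first-order histogram features,
    densitometric derivation of the LI-RADS major features (arterial-phase
    hyperenhancement from mean-HU differences, non-peripheral washout from the
    percentage attenuation ratio, threshold growth, size), an implementation of
    the LI-RADS v2018 CT diagnostic table with ancillary-feature adjustment and a
    machine-readable rationale trace, structured-report rendering with registry
    export, and agreement statistics (McNemar-Bowker test, exact sign test,
    percent agreement) for comparing visual and arithmetic readings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
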