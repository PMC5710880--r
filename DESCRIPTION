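Package: glandscreen
Title: Automated Histological Screening of Colorectal Biopsy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated four-way classification pipeline for H&E-stained
    colorectal biopsy tissue images (Positive, Adenoma, Negative,
    Unclassifiable), built for screening-style quality control of routine
    pathology. Implements tissue detection on slide overviews, focus and
    artifact quality control, stain-vector colour normalization, two-pass
    glandular structural atypia morphometry, a multi-instance-learning
    cytological atypia classifier, rule-based overall classification, and
    the screening error indices (undetected carcinoma, undetected adenoma,
    over-detected proportion). Ships a seeded synthetic H&E gland-image
    generator with per-pixel ground truth for calibration and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
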