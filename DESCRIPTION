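Package: cardioplane
Title: Standard Plane Extraction from 3-D Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic extraction of the six cardiac standard planes (apical
    four-, three- and two-chamber; parasternal short-axis at mitral-valve,
    papillary-muscle and apex level) from 3-D echocardiographic volumes.
    Three anatomical landmarks (LV apex, septal and lateral mitral annulus)
    are localized with 3-D Hough forests using a coarse-to-fine hierarchical
    search; the six planes are initialized from the landmarks via guideline
    anatomical regularities (shared LV long axis, fixed inter-plane angles
    and short-axis fractions); each plane is then refined by a constrained
    regression forest that votes on a single angle (long-axis planes) or
    translation (short-axis planes) while the long axis stays fixed. A
    synthetic left-ventricle phantom generator with exact ground truth,
    augmentation and noise protocols allows the whole pipeline to be trained
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
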