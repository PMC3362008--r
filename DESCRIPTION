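Package: qfkin
Title: Quantitative Fluoroscopy of Continuous Intervertebral Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures continuous intervertebral motion of the lumbar spine
    from fluoroscopic image sequences. Provides vertebral template tracking by
    masked normalized cross-correlation with sub-pixel refinement, corner-based
    (Frobin-style) registration of vertebral position, and derivation of the
    consensus motion indices: ranges of intervertebral rotation and
    translation, neutral zone laxity, instantaneous axis of rotation,
    disc height, directional coherence, motion commencement sequence, phase
    lag and motion sharing. Includes a ground-truthed synthetic phantom
    generator emulating protocol-conformant acquisitions and harnesses for
    accuracy and repeatability evaluation, plus readers and writers for image
    stacks, landmark templates and kinematic results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    tiff,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
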