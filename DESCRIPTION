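Package: normgain
Title: Divisive Normalization, Adaptive Psychophysics and Cortical
    Surface-Area Screening for Motion Duration Thresholds
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how individual differences in cortical
    surface area relate to visual motion perception. Implements a spatial
    divisive-normalization model with a top-down attentional gain field
    that predicts motion duration thresholds across stimulus size and
    contrast; a Bayesian adaptive (Psi) staircase simulator with Weibull
    psychometric fitting and staircase quality control; parcel-level
    cortical surface-area normalization, region sums, group splits and
    brain-behavior correlation screening; block-design fMRI response
    extraction with motion and performance exclusion rules; a fully
    seeded synthetic cohort generator; and end-to-end pipelines that tie
    the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
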