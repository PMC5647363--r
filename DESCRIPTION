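Package: tursiops
Title: Dolphin Movement, Behavioural Budgets and Whistle Acoustics under
    Vessel Traffic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for shore-based studies of coastal dolphin
    responses to vessel traffic and underwater noise. Converts theodolite
    angle fixes to planar tracks and per-sample movement speeds, builds
    context-conditioned first-order Markov chains of activity states with
    stationary behavioural budgets and two-proportion Z-tests, computes
    calibrated broadband and octave-band noise levels from hydrophone
    pressure series, extracts whistle-contour characteristics, and fits
    AICc-selected generalised additive models linking whistle
    characteristics to noise and group context. Includes a synthetic
    survey generator with known ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    multcomp,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
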