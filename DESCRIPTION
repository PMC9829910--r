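Package: rivalscreen
Title: Simulation Engines for Tablet-Based Paediatric Vision Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, seedable engines for a tablet-based paediatric
    vision-screening protocol: an adaptive interocular brightness-disparity
    staircase played under binocular rivalry, a tumbling-E visual-acuity
    state machine with pinhole retest, and a digital Hardy-Rand-Rittler
    (AO-HRR) colour-vision test. Generative simulated observers (normal,
    unilateral amblyope, refractive error, treated amblyope, colour defect)
    drive the protocols so that screening performance (sensitivity,
    specificity, prevalence) and method agreement (Bland-Altman limits) can
    be studied without human subjects. Includes cohort simulation, session
    persistence as JSON, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
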