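Package: promet
Title: Evaluation Metrics for Myoelectric Prosthesis Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for quantitative evaluation of myoelectric prosthesis
    controllers from functional-task recordings. Segments object-relocation
    trials into movements and Reach/Grasp/Transport/Release/Home phases from
    hand and object kinematics, computes task-performance metrics (success
    rate, durations, peak hand velocity, hand distance travelled, hand
    trajectory variability) and control-characteristics metrics (grip
    aperture and wrist rotation excursion, adjustment counts, grip aperture
    plateau, simultaneous wrist-shoulder movement, total muscle activity),
    applies median/IQR rescaling rules to flag instances of the limb
    position effect, and runs a repeated-measures comparison pipeline
    (RMANOVA with Greenhouse-Geisser correction, Friedman, paired
    t/Wilcoxon). Includes a synthetic trial and cohort generator with an
    analytic ground-truth ledger for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
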