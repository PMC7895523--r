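Package: trapstroke
Title: Working-Stroke and Attachment-Kinetics Analysis for Three-Bead Optical Trap Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule myosin recordings from the
    three-bead (dumbbell) optical trapping geometry. Detects actomyosin binding
    events from the sliding-window covariance of the two bead positions
    (two-Gaussian peak decomposition, threshold-crossing detection, two-step
    refinement), builds time-forward and time-reversed ensemble averages of the
    event-aligned displacement to extract the total working stroke, its substeps
    and their rise rates, and fits dead-time-truncated single- and
    two-exponential models to attachment durations by maximum likelihood with
    log-likelihood-ratio model selection and bootstrap confidence intervals.
    Includes an Ornstein-Uhlenbeck bead-dumbbell simulator with ground-truth
    event bookkeeping so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
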