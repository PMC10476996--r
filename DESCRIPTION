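Package: oarclass
Title: Guideline-Aware Classification and Evaluation of Radiotherapy
    Structure Sets
Version: 0.1.0
Authors@R:
    person("Radiotherapy", "Informatics", email = "oarclass@example.org",
           role = c("aut", "cre"))
Description: Image-based classification of radiotherapy organ-at-risk
    delineations drawn under different delineation guidelines. Implements
    the full preprocessing chain from CT volumes and structure sets to a
    two-channel classifier input (z-score normalized CT plus an AddMap
    joint body/structure encoding), a custom-precision-driven training
    protocol with k-fold cross validation, majority-vote ensemble
    inference with structure-name-based exclusion, geometric segmentation
    metrics (Dice, 95th-percentile Hausdorff distance, mean surface
    distance) with superior truncation, a Wilcoxon signed-rank comparison
    harness, and a synthetic pelvic CT phantom factory providing two
    parametric guideline variants so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
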