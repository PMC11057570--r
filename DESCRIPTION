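Package: rmrs
Title: Robust Metabolic Syndrome Risk Score from Radar-Chart Triangular Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a continuous, sample-independent severity score for
    metabolic syndrome (MetS) from the five AHA/NHLBI risk factors. Each
    factor is normalized against its diagnostic cutpoint, mapped to (0,1)
    with an Elliot sigmoid so the cutpoint sits at 0.5, and all ten
    three-factor radar-chart triads are scored by triangular areal
    similarity (TAS), a blend of closeness to and severity beyond the
    diagnostic triangle. The root mean of the ten TAS scores gives the
    Robust MetS Risk Score (RMRS) in [0,1] with a structurally derived
    fixed diagnostic cutoff of 0.547. Includes an interaction-term
    reformulation of TAS, CSV cohort scoring, a Gaussian-copula synthetic
    cohort generator, ROC/Youden evaluation utilities, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
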