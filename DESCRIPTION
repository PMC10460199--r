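Package: aortaflow
Title: Aortic Flow Quantification from Phase-Contrast Velocity Maps and
    Exercise-Capacity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies two-dimensional phase-contrast aortic flow from
    time-resolved through-plane velocity maps with lumen masks: flow curves
    with forward/retrograde pixelwise decomposition, systolic landmarks,
    forward and backward flow volumes, systolic flow-reversal ratio, lumen
    area pulsatility (relative area change), flow displacement of the forward
    jet with rotational angle and speed under a laminar-flow gate, and
    transit-time pulse wave velocity by the half-maximum method. Includes the
    downstream cohort statistics used to relate these markers to peak oxygen
    uptake (stepwise linear regression, a published composite model, ROC with
    the Youden index, nested logistic likelihood-ratio tests) and
    method-agreement indices (two-way mixed consistency ICC, coefficient of
    variation, Bland-Altman limits), plus ground-truth simulators for
    velocity cines, flow-curve pairs, cohorts, and repeated measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
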