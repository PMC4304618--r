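Package: sugarhier
Title: Sugar-Utilization Hierarchy Analysis from Plate-Reader Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse the carbon-source utilization hierarchy of
    Escherichia coli from plate-reader time series of optical density and
    GFP reporter fluorescence. Implements extraction of growth rate and
    promoter activity (smoothed temporal derivatives, mid-exponential
    windowing), construction of row-normalized pairwise hierarchy and
    cross-activation matrices, fitting of linear CRP-cAMP regulatory input
    functions with leave-one-out prediction of the hierarchy, a classifier
    for sequential versus simultaneous promoter dynamics, and cost/benefit
    resource-allocation optimality models (bang-bang corner solutions,
    switch thresholds, convex-constraint co-expression, and a
    multi-objective Pareto variant). A mechanistic synthetic plate-reader
    generator, calibrated to published growth-rate and regulatory
    constants, replaces the robotic assay so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    jsonlite,
    stats,
    rlang,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
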