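Package: grazekit
Title: Sward Structure, Dietary Overlap and Nutritional Intake Analysis for
    Mixed Cattle-Antelope Grazing Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing interspecific foraging interactions between
    cattle and small grazing antelope on shared rangeland: sward structural
    heterogeneity (coefficient of variation of sward height) and greenness
    availability from transect quadrats, defoliation-regrowth calibration
    inverted to per-camp grazing frequency, bite-scale dietary contributions
    and Schoener's dietary overlap, dry-matter and crude-protein intake rates,
    and Gamma generalized linear model group comparisons. Includes a
    synthetic-data generator that emulates the statistical structure of a
    stocking-rate field study so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
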