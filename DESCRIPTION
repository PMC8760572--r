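Package: crvsddm
Title: Death Distribution Methods and Adult Mortality Estimation from
    Incomplete Vital Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the completeness of death registration and to
    estimate adult mortality when civil registration and vital statistics
    (CRVS) data are incomplete.  Implements the two-census death distribution
    methods - generalized growth balance (GGB), synthetic extinct generations
    (SEG) and the combined GGB-SEG adjustment - with an age-trim sensitivity
    sweep, abridged life-table construction yielding the probability of dying
    between ages 15 and 50 (35q15), life expectancy at age 15 (e15) and the
    female-male e15 gap, direct estimation of adult mortality from DHS-style
    sibling histories and household death modules, two-source registry
    comparison, and synthetic-data generators with known ground truth for
    validating every stage of the pipeline.
License: MIT
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
    withr,
    optparse
Config/testthat/edition: 3
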