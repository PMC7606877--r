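Package: alpdyn
Title: Population-Balance Modeling of Stem-Cell Proliferation and
    Osteogenic Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mean-field population-balance (Smoluchowski-type) modeling of
    human mesenchymal stem-cell cultures, tracking the distribution of
    per-cell alkaline-phosphatase (ALP) activity under cell division,
    terminal osteogenic differentiation, and intracellular ALP synthesis
    and degradation.  Provides a numerical solver for the full
    integro-differential balance equation on an activity grid, closed-form
    moment solutions for the progressive (PSCD) and instantaneous (ISCD)
    differentiation models, an event-driven stochastic single-cell
    simulator used as an independent oracle for the mean-field moments,
    nonlinear least-squares fitting of the closed forms to assay time
    courses (LDH cell counts and total ALP activity) with chi-squared
    goodness of fit, model discrimination between PSCD and ISCD, and a
    synthetic-assay generator emulating the control versus
    electrically-stimulated study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    withr
Config/testthat/edition: 3
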