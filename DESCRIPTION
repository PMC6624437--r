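Package: anfisopt
Title: Neuro-Fuzzy Modeling and Multi-Objective Optimization of Plant
    Tissue Culture Response Surfaces
Version: 0.1.0
Authors@R:
    person("anfisopt", "developers", email = "anfisopt@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling in-vitro plant phenotype responses with
    first-order Sugeno adaptive neuro-fuzzy inference systems (ANFIS) and
    for optimizing culture conditions with the elitist multi-objective
    genetic algorithm NSGA-II.  Includes a calibrated synthetic-data
    generator for a factorial somatic-embryogenesis experiment (plant
    growth regulators, carbohydrate sources, LED light quality),
    goodness-of-fit metrics (R2, RMSE, MBE), leave-one-feature-out
    variable-importance analysis (VSE/VSR), Pareto ideal-point selection,
    and an end-to-end pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
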