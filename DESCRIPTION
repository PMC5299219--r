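Package: igwokelm
Title: Wrapper Feature Selection with a GA-Seeded Grey Wolf Optimizer and
    Kernel Extreme Learning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binary wrapper feature selection for two-class tabular
    diagnostic data. Candidate feature subsets are scored by a closed-form
    regularized kernel extreme learning machine (RBF kernel) and searched by
    a grey wolf optimizer whose initial population is diversified by a
    single-pass genetic algorithm (roulette selection, single-point
    crossover, uniform mutation). Includes plain genetic-algorithm and plain
    grey-wolf baselines, a stratified repeated k-fold evaluation harness with
    confusion-matrix metrics (accuracy, sensitivity, specificity, precision,
    G-mean, F-measure), per-feature selection-frequency tables, parameter
    sweeps, a synthetic-data generator with known informative structure, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
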