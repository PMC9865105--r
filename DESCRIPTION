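Package: protacpd
Title: Mechanistic Pharmacodynamic Modeling of PROTAC-Mediated Protein
    Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative assessment and optimization of
    proteolysis targeting chimeras (PROTACs) from in vitro pharmacology
    data. Implements a three-model mechanistic framework: a hook model
    describing bell-shaped concentration-degradation profiles including
    the high-concentration hook effect, a kcat model linking ternary
    complex target engagement (binary affinities, cooperativity, E3
    ligase expression, protein turnover) to the extent and kinetics of
    degradation, and a direct-response PD model combining degradation
    and inhibition into a downstream pharmacodynamic readout. Provides
    nonlinear least-squares fitting with seeded residual-bootstrap
    confidence intervals and Welch comparisons, experimental-design
    utilities (minimum incubation time, concentration grids), forward
    prediction across cellular systems, a seeded synthetic-data
    generator, CSV data exchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
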