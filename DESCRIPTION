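Package: possMFA
Title: Possibilistic Metabolic Flux Analysis and Elementary-Mode Tools for
    Small Constraint-Based Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build, inspect and validate small constraint-based
    (stoichiometric) models of cellular metabolism.  Provides a plain-text
    reaction-table format, elementary flux mode enumeration with yield and
    macroreaction annotation, possibilistic metabolic flux analysis
    (consistency degrees, gamma-level flux intervals, prediction of
    non-measured fluxes), and variance-weighted least-squares consistency
    indices.  Ships a 44-reaction model of the central carbon metabolism of
    the methylotrophic yeast Pichia pastoris growing on glucose, glycerol
    and methanol, together with eleven published chemostat and fed-batch
    datasets and random rejection batteries used to exercise the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
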