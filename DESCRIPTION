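Package: slsorb
Title: Sanchez-Lacombe Modelling of Gas Sorption in PHBV Biopolymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice-fluid (Sanchez-Lacombe) thermodynamics for polymer-gas
    systems, oriented at CO2/CH4 separation in poly(3-hydroxybutyrate-co-
    3-hydroxyvalerate) (PHBV) copolymers. Fits characteristic parameters
    (T*, p*, rho*) to pressure-volume-temperature data by MAPE minimisation,
    derives copolymer parameters at arbitrary hydroxyvalerate content through
    lattice-fluid mixing rules, converts pressures to fugacities with the
    Peng-Robinson equation of state, and solves pure- and mixed-gas sorption
    equilibria to predict dissolved concentrations, solubility coefficients,
    matrix swelling, solubility-selectivity and binary-interaction
    sensitivity bands. Includes a synthetic PVT generator emulating
    molecular-dynamics density data for end-to-end testing, and a
    configurable pipeline runner.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
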