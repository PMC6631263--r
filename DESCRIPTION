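Package: slekit
Title: Solid-Liquid Equilibria and Eutectic Point Analysis for Deep Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling solid-liquid equilibria (SLE) in binary eutectic
    mixtures such as deep eutectic solvents (DES). Implements pure-component
    melting-property thermodynamics (including the Walden rule), liquidus-line
    calculation from the classical subcooled-liquid reference-state equation with
    an optional heat-capacity correction, Redlich-Kister liquid-phase activity
    coefficients, a robust eutectic-point solver with depression metrics,
    parameter sweeps over melting properties and non-ideality, back-fitting of
    melting properties from ideal-solubility linearization, Redlich-Kister
    coefficient regression, a melting-enthalpy screening workflow, and a
    synthetic SLE data generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
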