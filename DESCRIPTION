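Package: cycledissip
Title: Steady-State Thermodynamics of Unicyclic Enzyme Kinetic Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes steady-state catalytic and thermodynamic performance
    parameters for single-cycle (unicyclic) reversible enzyme kinetic schemes
    from microscopic rate constants: turnover number (kcat), Michaelis constant
    (KM), specificity constant (kcat/KM), net and one-way cycle fluxes,
    thermodynamic force, total dissipation, and the nonnegative edge-wise
    (partial) entropy production decomposition. Includes an optimizer that
    maximizes the partial entropy production of a chosen transition by varying
    its forward rate constant (single-edge and iterative two-edge variants), a
    power-law fitting pipeline for the dissipation-versus-efficiency scaling
    across enzyme ensembles (with paired-bootstrap slope comparison and a 3D
    dissipation-plane fit), a seeded generator of thermodynamically consistent
    synthetic scheme ensembles, and CSV readers/writers with row-level
    validation for rate-constant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
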