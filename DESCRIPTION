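Package: kinetrap
Title: Mass-Action Kinetics of Non-Catalytic Binders, Negative
    Catalysis, and Kinetic Trapping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models how a stoichiometric, non-catalytic binder shapes the
    outcome of slow spontaneous reactions. Converts free-energy barriers
    and destabilizations into first-order rate constants via transition-
    state theory; builds mass-action kinetic schemes for a uniform binder
    acting on an irreversible unimolecular reaction, for kinetic
    partitioning between two competing products under negative catalysis,
    and for coupling to a downstream irreversible reaction that releases
    the kinetically trapped product; integrates the schemes with
    stiff-capable ODE solvers; and computes the product-ratio, binder-
    occupancy and rate-invariance observables on which such models are
    judged. Includes a seeded synthetic-scenario generator for
    property-style testing and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
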