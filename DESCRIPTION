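Package: moorings
Title: Agent-Based Simulation of Coastal Migration and Moored Populations
    Under Sea-Level Rise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale agent-based model of livelihood-driven internal
    migration under sea-level-change flooding, in the push-pull-mooring
    tradition. Individual agents hold portfolios of located income
    opportunities ("utility layers"), share information and resources over a
    dynamic weighted social network, and reconsider their livelihoods with
    boundedly rational, prospect-theoretic valuation subject to wealth and
    credit constraints. Rising seas raise annual peak flood depths; flooding
    beyond what agents perceive as normal damages wages and reshapes the
    migration landscape. The package provides a synthetic-world generator
    (districts, income layers, populations, observed flow matrices),
    demographic and hazard processes, the quarterly simulation engine, a
    calibration harness over the five decision-sensitive parameters, and an
    ensemble driver with analyses of net migration, moored (credit-constrained
    immobile) populations, and parameter importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
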