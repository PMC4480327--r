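Package: weedfitness
Title: Trait-Based Population Dynamics and Fitness Landscapes for Annual Weeds
Version: 0.1.0
Authors@R: person("WTDB", "Tools", email = "wtdb.tools@example.org", role = c("aut", "cre"))
Description: Tools for storing and summarising functional-trait records of
    annual arable weeds, fitting the empirical regressions that link maximum
    plant height and seed weight to demographic parameters (allometric
    fecundity intercept, maximum emergence depth, and competitive ability
    expressed as the weed density causing 5% crop yield loss), and running a
    generic single-season life-cycle model that returns the population growth
    rate lambda. Lambda is swept over a height-by-seed-weight trait grid under
    herbicide and fertility management scenarios to produce fitness contours,
    onto which real or simulated species pools are projected and classified as
    growing (lambda >= 1) or declining. Includes a one-at-a-time sensitivity
    analysis, seeded synthetic-data generators for all inputs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
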