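Package: limnet
Title: Linear Inverse Modeling and Ecological Network Analysis of
    Food-Web Carbon Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Specifies steady-state food-web carbon-flow models as
    constrained linear systems (mass-balance equalities, measured flows,
    ecological inequality bounds), samples the feasible flow polytope
    uniformly with a mirror Markov chain Monte Carlo walk, and computes
    Ecological Network Analysis indices (total system throughput, average
    mutual information, ascendency, development capacity and its overhead
    partition, Finn cycling index, average path length, Lindeman trophic
    aggregation) for single flow vectors and whole sample ensembles.
    Ships the Lake Pavin spring-bloom plankton models with and without
    parasitic chytrid fungi, a synthetic food-web problem generator with
    brute-force sampling oracles, and tools for the statistical comparison
    of two model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
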