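Package: perishvi
Title: Batched Value Iteration and Simulation for Perishable Inventory Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and heuristic replenishment policies for periodic-review
    perishable inventory problems formulated as finite Markov decision
    processes. Provides a generic batched value-iteration solver built on the
    deterministic-transition-over-random-outcomes factorisation, three
    ready-made scenario models (single product with delivery lead time and
    truncated gamma demand; two substitutable products with Poisson demand;
    a hospital platelet bank with weekday-periodic demand and uncertain
    remaining shelf life on arrival), matched seeded stochastic simulators
    with service-level, wastage and holding KPIs, parametric heuristic
    policies (base-stock, waste-adjusted base-stock, weekday (s,S)) fitted by
    simulation optimization, and a reproduction harness driven by YAML
    experiment configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
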