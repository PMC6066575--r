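Package: fairplay
Title: Evolutionary Agent-Based Simulation of Juvenile Fair Play and Adult
    Resource Pooling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based model of the evolution of juvenile fair play in
    group-structured populations. A single heritable play gene lets juveniles
    engage in pairwise play bouts (with a per-bout mortality risk); juveniles
    that play enough bouts learn adult fairness, i.e. pooling each step's
    foraging gains with other fair group members and dividing the pool
    equally. Reproduction is gated by a resource threshold, fractional
    parental investment, and a minimum delay between reproductive events.
    The package runs single seeded simulations, factorial parameter sweeps
    with matched controls, and the closed-form payoff-variance and
    binomial-threshold analytics that explain when selection favors fairness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
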