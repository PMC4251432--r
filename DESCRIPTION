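Package: ldgsim
Title: Simulating Latitudinal Diversity Gradients Under Competing
    Macroevolutionary Hypotheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of clade diversification and dispersal
    along a one-dimensional thermal gradient of ten regions, under four
    scenarios: pure niche conservatism (no energetic limits), an energy
    gradient in regional carrying capacity, a speciation-probability
    gradient, and a disturbance-magnitude gradient.  Includes the
    diagnostic statistics used to fingerprint each scenario: the
    latitude-richness and occupancy-time-richness Pearson correlations,
    the slope of scaled mean root distance on regional richness, Aldous
    beta-splitting tree imbalance estimated by maximum likelihood, and
    tip-level speciation-rate estimators (equal-splits and realized
    per-lineage rates from the event log).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
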