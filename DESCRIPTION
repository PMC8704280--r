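Package: pollinet
Title: Elevational Analysis of Plant-Pollinator Interaction Networks
Version: 0.1.0
Authors@R:
    person("pollinet", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bipartite plant-pollinator interaction
    networks sampled along environmental gradients. Builds site-level and
    pooled interaction-count matrices from specimen-level visitation
    records; computes weighted connectance, NODF nestedness, Barber
    bipartite modularity, H2' network specialization and secondary-
    extinction robustness; identifies core generalist pollinators via a
    degree z-score (Gc) and nested ranks; simulates targeted pollinator
    removals and tracks the resulting change in nestedness; compares
    richness and abundance across habitat zones with generalized linear
    models and Tukey-adjusted pairwise marginal-mean contrasts; and
    provides a seeded trait-matching community generator so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
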