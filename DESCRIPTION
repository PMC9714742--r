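Package: replinet
Title: Compartmentalized Host-Parasite Replicator Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of translation-coupled RNA replicator
    networks in water-in-oil compartments. Implements coupled logistic
    cross-replication dynamics within compartments, a serial
    replication-culling-fusion-division cycle, sustainability sweeps over
    replication-coefficient grids for two- and three-member host-parasite
    networks, an evolutionary-transition simulator with stochastic
    appearance of new host and parasitic species, and estimation of
    replication coefficients from two-step fold-change assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    seqinr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
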