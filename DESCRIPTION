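Package: ca3balance
Title: Pattern Separation and Completion Balance in an Autoassociative
    CA3-Like Network Model
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation of a hippocampal-CA3-like autoassociative memory
    network of 100 conductance-based excitatory point neurons with feedback
    inhibition. Implements Hebbian LTP/LTD weight formation from coactivation
    statistics of random stimulus patterns, pattern-separation and
    pattern-completion assays within a single gamma cycle (by explicit
    Hodgkin-Huxley simulation or a precomputed spike-threshold-table fast
    path), exhaustive parameter-grid sweeps to identify optimal balanced
    wild-type networks, and an in-silico pathology and therapeutics analysis
    that classifies separation versus completion bias and prescribes
    rebalancing manipulations of LTP, LTD, inhibition, or connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
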