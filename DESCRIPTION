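Package: critmodes
Title: Criticality and Internal/External Processing Modes in Oscillator Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of delay-coupled Stuart-Landau oscillator
    networks on structural brain connectomes, and of multichannel band-limited
    signals, to study how proximity to criticality shapes the network's
    alternation between internally integrative and externally susceptible
    processing modes. Provides the Kuramoto order parameter, pair correlation
    function, window-wise susceptibility, ordinal-pattern symbolic mutual
    information with phase-randomized surrogate filtering, weighted phase lag
    index connectivity, degree-amplitude topographic similarity, dwell-time
    power-law versus exponential model comparison, and co-activation pattern
    extraction with permutation testing, together with synthetic generators for
    connectomes, EEG-like signals, and parcel BOLD with planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
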