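Package: nmdanet
Title: Spiking Networks with Exact and Jump-Approximated NMDA Receptor Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator for conductance-based leaky integrate-and-fire networks
    with AMPA, GABA and NMDA receptor currents. Implements both the original
    two-variable NMDA gating model and an asymptotically matched jump
    approximation whose per-spike update constants derive from the lower
    incomplete gamma function, permitting aggregated postsynaptic simulation
    under arbitrary connectivity and delay distributions. Includes the
    winner-take-all binary decision-making network, sparse-network clamp
    protocols, Poisson and coherence-modulated stimuli, and analysis tools
    (binned population rates, Weibull psychometric fits, bootstrap confidence
    intervals).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
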