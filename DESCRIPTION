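Package: titinsim
Title: Passive Titin Forces in Half-Sarcomeres Under Length-Ramp Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic model of the passive force contributed by titin
    strands in a half sarcomere during length-ramp experiments. A titin
    strand is a series chain of worm-like-chain (WLC) and linear-spring
    elements whose proximal immunoglobulin (Ig) domains unfold (and refold)
    in a force- and time-dependent manner following Bell kinetics. The
    package solves the single-strand mechanical equilibrium for every
    possible number of unfolded domains, simulates ensembles of strands by
    fixed-step Monte Carlo, and computes the exact probability distribution
    of unfolding states through the linear master equation (implicit Euler
    on the cluster-occupancy state space), from which expected forces,
    first-unfolding-force distributions and hysteresis analyses are
    derived. The two routes cross-validate each other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
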