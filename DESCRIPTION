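Package: endotaxis
Title: Neural-Circuit Map Learning, Goal Navigation, and Patrolling on Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis library for endotaxis, a neuromorphic
    algorithm in which an agent learns a cognitive map of a graph-structured
    environment through Hebbian plasticity in a recurrent map network, tags
    resource locations with goal cells, and navigates by greedy ascent of the
    resulting internally generated "virtual odor" signal. Provides built-in
    environment graphs (rings, binary-tree labyrinths, Tower-of-Hanoi state
    graphs), closed-form theory quantities (resolvent and goal-signal
    matrices, critical gain), exploration-based learning with optional
    forgetting, noisy greedy navigation with exact expected route lengths via
    absorbing Markov chains, habituation-driven patrolling, and scenario
    runners for homing, link-change timelines, and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
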