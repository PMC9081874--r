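Package: wcnet
Title: Connectome-Coupled Wilson-Cowan Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building, analysing and evaluating whole-brain network
    models in which each cortical region is a Wilson-Cowan excitatory and
    inhibitory neural-mass pair, coupled through a directed binary connectome
    by a global coupling constant. Provides single-node bifurcation analysis
    in the net-input coordinate (equilibrium continuation, saddle-node and
    Hopf detection, limit-cycle envelopes, regime classification), stochastic
    network simulation by the Euler-Maruyama method, cell-density-driven
    regional heterogeneity of coupling weights, functional-connectivity
    scoring against a target FC matrix (Spearman FC-FC score), parameter
    sweeps with seed replicates, and a permutation test against shuffled
    cell-density maps. A synthetic-data module generates connectomes,
    density maps and target FC matrices so every stage runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
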