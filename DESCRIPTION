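Package: glycopore
Title: Comparative Trajectory Analysis of Pore-Facing Glycan Effects in
    Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular dynamics trajectories of
    pentameric ligand-gated ion channels (GABA-A receptor assemblies and
    synthetic stand-ins), quantifying how pore-facing N-glycans perturb
    subunit interfaces and channel gates. Implements geometric salt-bridge
    and hydrogen-bond occupancy networks with cross-system comparison
    filters, extracellular-domain expansion via convex-hull area of subunit
    centers of mass, internal-loop RMSD and RMSF with stable-core
    superposition, glycan anchor and terminal-sugar tracking, HOLE-style
    maximal-inscribed-sphere pore radius profiling with gate traces and
    closure probabilities, water occupancy histograms and water-wire
    continuity, permeability contingency tests, and correlation-weighted
    dynamical network analysis with suboptimal path enumeration,
    betweenness centrality and cross-replica hub conservation. Includes a
    seeded synthetic pentamer-trajectory generator that plants exactly
    known contacts, gate schedules, water placements and correlated
    motions so every analysis stage is verifiable against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    bio3d,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
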