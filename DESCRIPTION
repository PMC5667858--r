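Package: AlloDyn
Title: Ensemble Dynamics, Allosteric Networks and Rigidity Analysis of Protein Kinases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Event-driven discrete molecular dynamics of coarse-grained
    square-well Go models, Gaussian network model mode analysis and
    perturbation-response scanning, conservation- and mutual-information
    weighted residue interaction networks with community and shortest-path
    analysis, and pebble-game rigidity decomposition with hydrogen-bond
    dilution for weak-spot detection. Includes synthetic structure, ensemble
    and alignment generators with planted ground truth so every stage of the
    pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
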