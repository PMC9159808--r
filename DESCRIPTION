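Package: holopls
Title: Molecular Hologram Fingerprints and PLS-DA Classification of
    Efflux-Transporter Inhibitors
Version: 0.1.0
Authors@R:
    person("holopls", "maintainers", email = "holopls@example.org",
           role = c("aut", "cre"))
Description: Ligand-based classification of ABCG2 (BCRP) efflux-transporter
    inhibitors from 2D structure. Implements HQSAR-style molecular hologram
    fingerprints (exhaustive connected-fragment enumeration, canonical
    fragment keys under configurable atom/bond distinctions, CRC-32 hashing
    into fixed-length count vectors), PLS-DA with NIPALS and cross-validated
    component selection, stepwise linear-regression descriptor selection,
    a single-descriptor threshold rule, a two-stage integrative classifier,
    atomic contribution mapping, confusion-matrix metrics (ACC/SEN/SPE/MCC),
    MaxMin Tanimoto diversity selection on circular fingerprints, and a
    seeded synthetic fixture generator so the whole pipeline is testable
    without proprietary descriptors or licensed software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
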