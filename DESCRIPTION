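Package: kinaconf
Title: Conformational and Interaction Analysis of Kinase MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of molecular dynamics trajectories of protein
    kinase domains, built around the analyses that discriminate active
    (DFG-in) from inactive (DFG-out) conformations of the ROS1 kinase
    domain: a three-residue DFG rotation-angle statistic with per-frame
    state classification, a grid-based ATP-binding-pocket volume, and
    occupancy networks of salt bridges, hydrogen bonds and hydrophobic
    contacts aggregated over concatenated replica trajectories. Includes
    a synthetic-trajectory generator with exact ground truth for every
    statistic, a configuration-driven pipeline, and CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
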