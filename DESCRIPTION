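Package: ettnir
Title: Optical Monitoring of Endotracheal Tube Displacement by
    Near-Infrared Transillumination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for optical monitoring of
    endotracheal tube (ETT) position. Implements a layered-slab Monte
    Carlo model of 810 nm photon transport from a side-firing fiber on
    the tracheal lumen to the chest skin, a forward model of a
    five-phototransistor detector board with its amplifier and RC
    filter chain, ratio-based second-order polynomial calibration with
    branch inversion and weighted fusion into a displacement estimate,
    a seeded generator of synthetic monitoring sessions emulating
    ex vivo and in vivo protocols, and regression plus Bland-Altman
    agreement analysis of estimated versus reference displacement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
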