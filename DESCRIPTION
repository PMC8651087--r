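Package: myxosim
Title: Agent-Based Simulation of Myxococcus xanthus Gliding and Circular
    Aggregate Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biophysical agent-based simulator of Myxococcus xanthus
    gliding motility. Cells are flexible rods of spring-connected nodes with
    distributed propulsion, viscous drag, substrate focal-adhesion springs,
    capsule collision resolution, slime-trail deposition and following,
    allele-aware cell-cell adhesion bonds, and a reversal clock that is
    suppressed by sustained cell contacts. Includes an analysis toolkit for
    reversal statistics, detection of rotating circular aggregates, radial
    kinematic profiles and contact-suppression summaries, together with
    canned computational experiments (phenotype matrix, reversal-period and
    adhesion-strength sweeps).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
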