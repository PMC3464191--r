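Package: chancav
Title: Pore, Cavity and Ligand-Exchange Analysis for Pentameric Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for pentameric ligand-gated ion channels:
    HOLE-style pore radius profiles with windowed constriction minima, grid-based
    consensus cavity detection with five-fold symmetrization and Monte-Carlo
    volumetrics, M2 helix kink angles from principal axes of inertia, per-cavity
    ligand/water/lipid occupancy series and number-density maps, occupancy
    autocorrelation with double-exponential exchange-time fitting, and
    occupancy-correlation statistics.  Includes a synthetic pentameric-channel
    trajectory generator with full ground truth so every stage is testable
    without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
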