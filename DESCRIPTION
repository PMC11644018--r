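Package: hbkinetics
Title: Hydrogen-Bond Dynamics and Connectivity Patterns in Water
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for hydrogen-bond (HB) kinetics in liquid and
    supercritical water. Detects hydrogen bonds in 3-site water trajectories
    under a triple criterion (pair interaction energy, H..O distance, donor
    OH inclination angle), computes connectivity patterns (clusters, patches
    of four-bonded molecules, the degree-of-connectivity parameter),
    continuous / intermittent / monomer time autocorrelation functions,
    survival-probability mean lifetimes with Student-t confidence intervals,
    and temperature-dependence fits (two-exponential decay, transition-state
    theory, linear monomer law). Includes synthetic generators with known
    ground truth (two-state Markov bond processes, planted HB motifs) and a
    scaled-down NVE molecular-dynamics engine for flexible 3-site water with
    Ewald electrostatics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
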