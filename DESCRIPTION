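Package: protonhop
Title: Proton-Exchange Moves and Transfer-Aware Transport Analysis for
    Particle Simulations of Protic Ionic Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level proton-transfer moves during particle dynamics
    using a single-topology representation with two discrete protonation
    states per residue. Provides dual-state residue templates with
    Drude-oscillator parameter transforms, distance- and probability-gated
    exchange moves with a cubic feedback rule that holds species counts
    near a reference partitioning, a minimal Brownian-dynamics engine for
    desk-scale demonstrations, and transfer-aware analyses: diffusion
    coefficients from segment-cut mean-squared displacements, ionic
    conductivity from the collective translational dipole moment with
    per-transfer corrections, and shell-resolved potentials of mean force.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
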