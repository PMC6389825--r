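Package: noddimc
Title: Monte Carlo Diffusion MRI Simulation and NODDI Fitting for
    Extra-Neurite Cellularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how cell density in the extra-neurite space
    shapes multi-compartment diffusion MRI measures. Provides a lattice-free
    Monte Carlo simulator of restricted water diffusion in a periodic tissue
    voxel built from hexagonally packed undulating cylinders (axons) and
    randomly placed impermeable spheres (microglia); synthesis of pulsed
    gradient spin-echo signals from the simulated spin trajectories;
    fitting of the NODDI three-compartment model (Watson-dispersed sticks,
    tortuous extracellular space, free water, and an optional isotropically
    restricted fraction for fixed tissue) and of the diffusion tensor; rank
    and t statistics plus particle counting for repopulation-style
    experiments; and seeded generators for synthetic diffusion signals,
    cell-count tables, and fluorescence-like images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
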