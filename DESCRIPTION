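Package: lamellipid
Title: Lamellarity-Resolved Analysis of Anionic Phospholipid Bilayers
Version: 1.0.0
Authors@R:
    person("Lamellipid", "Developers", email = "lamellipid@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for distinguishing multilamellar (ML) from
    unilamellar (UL) phospholipid membranes, built around solvated-bilayer
    trajectories and thermotropic melting data. Provides a plain-text
    trajectory data model with periodic-geometry primitives; seeded
    synthetic generators for DPPS/DPPG bilayer pseudo-trajectories,
    temperature-dependent absorbance matrices and DSC thermograms with
    known ground truth; membrane structure descriptors (area per lipid,
    mass density profiles, P-P thickness, deuterium order parameters,
    lateral diffusion); interfacial-water analyses (radial distribution
    functions, hydration-shell assignment, angular ordering versus
    distance, dipole tilt profiles, Einstein-relation diffusion);
    geometric hydrogen-bond detection with per-class and per-molecule
    normalisation plus cation contacts; bilinear (truncated SVD)
    decomposition of melting spectra with single/double Boltzmann fitting,
    DSC onset/maximum extraction, and fluctuation-based estimators of heat
    capacity, area compressibility and bending modulus. A pipeline runner
    produces UL-versus-ML comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
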