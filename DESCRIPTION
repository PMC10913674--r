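Package: dynED
Title: Dynamical 3D Electron Diffraction Intensities by Bloch Waves and the
    Scattering Cluster Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dynamical electron diffraction intensities for
    zone-axis-oriented crystals, as used in 3D electron diffraction (3D-ED /
    MicroED) of small-molecule and macromolecular crystals. Provides a
    Bloch-wave reference solver (Hermitian eigen-decomposition of the
    structure matrix with exact depth propagation) and a scattering cluster
    algorithm that truncates the structure matrix to couplings within a
    reciprocal-space cluster radius, filters weakly excited beams by a
    maximum deviation parameter, and integrates the coupled beam equations
    slice by slice.  Includes crystal-structure handling (CIF input, toy
    fixture generators), electron atomic scattering factors, structure
    factors and extinction distances, zero-order-Laue-zone beam geometry,
    precession electron diffraction averaging, and R-factor convergence
    metrics.
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
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
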