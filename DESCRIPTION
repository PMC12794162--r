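Package: pmmspectra
Title: Ensemble Absorption Spectra of Chromophores by the Perturbed Matrix Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes ensemble UV-vis absorption spectra of a chromophore
    embedded in a fluctuating electrostatic environment using the Perturbed
    Matrix Method (PMM): per-frame perturbed electronic Hamiltonians are built
    from gas-phase reference states and the environment's potential and field
    at the quantum-center expansion point, diagonalized, and accumulated into
    Gaussian-broadened extinction spectra. Includes dihedral-based
    conformational basin classification of flavin butterfly bending,
    essential-dynamics (positional-covariance) PCA, population weighting of
    basin spectra, charge-perturbation counterfactuals, and a synthetic-data
    generator that emulates the fluctuating point-charge environment and the
    three-basin bending process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
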