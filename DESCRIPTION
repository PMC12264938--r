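Package: lambdapose
Title: Binding-Pose Ranking with Lambda-Dynamics Alchemical Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale alchemical free-energy toolkit for ranking two
    alternative binding poses of a ligand with dual-topology
    lambda-dynamics. Provides toy dual-pose particle systems with an exact
    quadrature free-energy oracle, the hybrid Hamiltonian (FNEX lambda
    parameterization, soft-core pair potentials, adaptive flattening
    biases), flat-bottom distance restraints with trajectory-statistics
    selection, Langevin samplers over coordinates and alchemical
    variables, and a suite of free-energy estimators (endpoint
    populations, histogram reweighting, Zwanzig one-step perturbation,
    windowed FEP/MBAR) assembled into a thermodynamic cycle with
    propagated uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
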