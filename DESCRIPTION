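Package: boronfit
Title: AMBER Force-Field Parameterization Toolkit for Boronate Covalent Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and validating AMBER force-field torsion
    parameters for boron-containing covalent ligands (boronate warheads bound
    to a serine nucleophile). Provides a typed parameter store with a built-in
    boronate dihedral/bond/angle library, AMBER frcmod reading and writing,
    an AMBER-functional-form molecular-mechanics energy over multi-conformer
    Cartesian coordinate sets, a least-squares torsion fitter against quantum
    single-point energies with an analytically profiled offset constant and
    coefficient of determination, systematic torsion-scan structure
    generation with coverage checks, Boltzmann equilibrium conformer
    populations, and circular-statistics basin analysis of torsion
    trajectories with comparison against reference conformer minima.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
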