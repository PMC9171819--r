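Package: chbe
Title: Chelator-Based Parameterization of 12-6-4 Lennard-Jones Metal-Ion Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving pairwise C4 (ion-induced-dipole) coefficients of the
    12-6-4 Lennard-Jones nonbonded potential from chelator binding free energies.
    Fits the linear response of simulated metal-chelator binding energies to the
    C4 coefficients of the ligating oxygen and nitrogen atoms, back-extrapolates a
    zero-C4 reference energy, and solves a denticity-scaled two-chelator linear
    system for unique oxygen and nitrogen coefficients. Also provides radial
    distribution function analysis (ion-oxygen distances from quadratic peak fits,
    coordination numbers from first-shell integration), conversion of experimental
    stability and dissociation constants to binding free energies, and a seedable
    Metropolis Monte Carlo sampler of ion-solvation shells for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
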