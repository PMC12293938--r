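Package: dimerdna
Title: Classical Dimer Model Partition Functions and DNA Charge Inversion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact partition functions for the classical dimer model on finite
    rectangular lattices at complete filling, via three mutually validating
    routes: symbolic expansion of traces of anticommuting link fields, the
    Pfaffian of the serpentine-ordered antisymmetric activity matrix, and the
    analytic closed form obtained from the cruciform block diagonalization.
    Reduces the two-leg ladder to the one-dimensional monomer-dimer-vacancy
    chain and provides its closed-form thermodynamics (per-site free energy,
    entropy, species occupancies, net charge), together with a non-interacting
    lattice-gas baseline. Includes an application to dimeric polyions adsorbing
    on the DNA backbone: entropy plateau, occupancy mixing and charge inversion
    as functions of the dimensionless binding energy.
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
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
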