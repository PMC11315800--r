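Package: chemion
Title: Minimal-Basis Vertex-Orbital Quantum Chemistry for Torsion Scans of
    Chain Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of an Euler-Hueckel vertex-orbital
    picture of singly bound molecules: one spherical Slater orbital per bonding
    site (central atom, hydrogen ligand, or lone pair), proportional nuclear
    charges per chemion ensemble, restricted Hartree-Fock and full
    configuration interaction in the resulting minimal basis, recursive vertex
    condensation of integral and Fock blocks with a persistent fragment bank,
    and drivers that reduce the n-dimensional torsion space of a flexible
    chain molecule to n one-dimensional potential curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
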