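Package: parrotbite
Title: Dissection-Based Bite-Force Estimation and Phylogenetic Allometry for Parrots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates bite force in parrots (Psittaciformes) from in-situ
    jaw-muscle dissection measurements via a physiological cross-sectional
    area (PCSA), torque and third-class lever model; fits log-log allometric
    relationships between bite force and body-size traits with
    phylogenetically controlled generalised least squares (Pagel's lambda);
    tests scaling exponents against isometric expectations; compares
    calculated against measured bite forces with a phylogenetic ANCOVA; and
    fits a power-law predictor of bite force from the adductor mandibulae
    externus muscle scar on the mandible. Includes a synthetic-data
    generator (Yule trees, Brownian trait evolution, forward-consistent
    specimen tables) so every pipeline stage is testable without cadaver
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    withr,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
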