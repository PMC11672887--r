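Package: orbdecomp
Title: Finite-Element Simulation of Orbital Decompression Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the soft-tissue outcome of orbital
    decompression surgery in thyroid eye disease. Generates parametric
    synthetic orbital labelmaps (bone, fat, muscle, bulbus, temporalis)
    with exact geometric ground truth, converts labelmaps to labelled
    tetrahedral meshes, encodes surgical plans (wall resection and
    lateral valgization of a hinged wall fragment) as boundary
    conditions, solves the displacement form of isotropic linear
    elastostatics with linear tetrahedral finite elements (optionally
    in incremental load steps with geometry updates), computes released
    intraorbital tissue volume, volume-per-area efficiency and
    proptosis change, and estimates identifiable tissue parameters
    (pressure-to-stiffness ratio, stiffness ratios, Poisson ratio) from
    observed outcomes by derivative-free optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
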