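Package: memwrap
Title: Adhesion-Energy Modelling of Multivalent Particle Wrapping and
    Membrane Tubulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling lipid-binding-mediated, clathrin-independent
    endocytosis of multivalent globular particles. Maps receptor affinity to
    an effective membrane adhesion energy, computes the wrapping threshold
    for a particle of given size and membrane bending rigidity, and finds
    minimum-energy axisymmetric membrane shapes for single-particle wrapping
    and joint tubular wrapping by constrained minimization of Helfrich
    bending plus adhesion energy. Also includes a maximum-likelihood
    change-point estimator for binary membrane-deformation outcome tables,
    object-based colocalization quantification for two-channel image stacks,
    and seeded synthetic-data generators for all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
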