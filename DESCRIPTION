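Package: osmometry
Title: Turgor Pressure Estimation from Protoplast Osmometry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates turgor pressure in walled yeast cells from protoplast
    measurements, treating protoplasts as ideal osmometers. Three independent
    methods locate the isotonic sorbitol concentration: Boyle Van't Hoff fits
    to 3D cell-volume data, calibrated cytoplasmic fluorescence intensity, and
    nanoparticle (cytGEMs) diffusion fitted to the Phillies equation. Isotonic
    concentrations are converted to pressure with the Van't Hoff relation,
    combined across methods with error propagation, and extended to thin-shell
    cell-wall mechanics (Young's modulus and wall tension). Includes seeded
    synthetic-data generators for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
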