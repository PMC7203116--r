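Package: pilihelix
Title: Helical Symmetry, Filament Models and Curvature Analysis for Type IV Pili
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the computational chain behind helical
    reconstruction of bacterial type IV pilus filaments: lattice arithmetic
    connecting pitch, subunits per turn, rise and twist; rational helical
    repeats and the Bessel selection rule for layer-line indexing; symmetry
    expansion of a pilin subunit into filament coordinate models (PDB);
    simulation of filament projection images and power spectra with
    layer-line detection and symmetry-candidate scoring; inter-subunit
    contact and salt-bridge analysis; and curvature profiling and
    classification of traced filament centrelines. Includes seeded synthetic
    generators for every input, each paired with a machine-readable
    ground-truth record.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
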