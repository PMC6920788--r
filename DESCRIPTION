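Package: memwet
Title: Wetting of Transmembrane Proteins by Liquid-Ordered Lipid Domains
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum elastic and thermodynamic model of liquid-ordered
    ("raft") lipid domain formation around a rigid cylindrical transmembrane
    protein by the wetting mechanism. Solves the tilt + splay (Hamm-Kozlov)
    membrane deformation problem in cylindrical coordinates for a bilayer with
    leaflet-resolved ordered annuli, evaluates the elastic grand potential,
    converts it to chemical potential and total free energy under
    subsaturation, and classifies equilibrium domain size and stability as a
    function of protein radius and boundary-director shape. Includes a
    brute-force finite-difference variational oracle, phase-portrait scans
    over transmembrane-domain shapes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
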