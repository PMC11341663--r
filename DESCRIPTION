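Package: aortafract
Title: Fracture Mechanics of Aortic Dissection Tear Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-analytical fracture-mechanics model of aortic dissection in a
    plane-strain cross-section. Solves the finite-strain equilibrium of the
    normal (uncracked) aortic annulus as an incompressible thick-walled
    cylinder and of the dissected cross-section as a two-segment nonlinear
    membrane, for Neo-Hookean, Gent and Holzapfel-Gasser-Ogden (HGO)
    constitutive models. Computes total potential energies per unit length and
    the energy release rate G for tear propagation in the longitudinal and
    circumferential directions, normalized as G/(mu*R). Includes parameter
    sweeps over pressure, wall thickness, tear depth and crack angle, a
    pressure/tear-depth safety map against the tissue fracture energy
    Gamma/(mu*R), and independent brute-force oracles (Rayleigh-Ritz energy
    minimization, constrained membrane minimization, small-strain Lame limit,
    finite-difference energy release rates) used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
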