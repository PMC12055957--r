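Package: capsuleflow
Title: Compound Viscoelastic Capsule Dynamics in Microchannels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transit of compound viscoelastic capsules (a cell
    with a nucleus) through constricted and cross-slot microchannels using an
    immersed boundary-lattice Boltzmann method. The cell membrane combines
    Skalak strain-hardening elasticity, surface shear viscosity and Helfrich
    bending resistance; the suspending fluid follows a truncated power law.
    Includes deformability-cytometry shape metrics (deformation index, Taylor
    parameter, mean Hausdorff distance) and the inverse-fitting pipeline that
    turns observed cell contours into membrane elastic moduli, membrane
    viscosity and initial off-centre distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
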