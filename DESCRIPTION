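Package: stenoflow
Title: Micropolar Blood Flow Through Catheterized Tapered Arteries with
    Overlapping Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical steady-flow model of blood, treated as an Eringen
    micropolar fluid, moving through the annular gap between a catheter and a
    tapered arterial wall bearing an overlapping (two-humped) stenosis, under
    the mild-stenosis (lubrication) approximation with velocity slip at the
    arterial wall.  Provides the wall-profile geometry and its extremum
    locations, the modified-Bessel-function solution for axial velocity and
    microrotation at each axial station, closed-form flux coefficients, flow
    impedance by adaptive quadrature, and wall shear stress, together with
    independent oracles (Newtonian annulus closed form, quadrature flux,
    derivative sign-scan), a flat-file configuration reader, parameter sweeps,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
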