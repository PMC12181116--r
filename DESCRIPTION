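Package: cortexgauge
Title: Gauge-Theoretic Neural Field Simulation on the Cortical Sheet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates neural field dynamics on the cortical sheet as a
    Klein-Gordon wave equation whose mass and propagation speed derive from
    local connectivity gains, couples the field to an abelian (U(1))
    connectivity potential whose Gauss-law solution yields a non-linear
    Hebbian learning rate, treats slow extrinsic-connectivity change as
    Robertson-Walker metric dynamics on a curved surface, and provides an
    SU(2) multilayer sector with closed-form generalized oscillations.
    Includes a laminar local-field-potential forward model (two- and
    three-layer rotating decaying waves) with Levenberg-Marquardt parameter
    inversion, plus differential-geometry utilities (Laplace-Beltrami
    operator, Christoffel symbols, Ricci scalar, Einstein tensor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
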