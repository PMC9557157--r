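Package: laaoflow
Title: Left Atrial Appendage Occlusion Hemodynamics Under LVAD Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics of left atrial appendage
    occlusion (LAAO) in patients supported by a continuous-flow left
    ventricular assist device (LVAD). Provides a closed-loop lumped-parameter
    model of the circulation with time-varying elastance chambers, diode
    valves, Windkessel vascular beds and a quadratic pump head-flow law;
    sinus-rhythm and atrial-fibrillation scenarios with and without appendage
    occlusion; a parametric mitral-valve surface generator; an idealized
    labeled left-atrium plus appendage flow domain with an occlusion switch;
    a pulsatile incompressible projection-method flow solver on a staggered
    masked grid; and thrombosis-related flow metrics (stagnation volume, wall
    shear stress classification, velocity statistics) together with
    virtual-ink washout and appendage blood-residence quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
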