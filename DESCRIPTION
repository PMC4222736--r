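Package: mplvr
Title: Non-Invasive Estimation of Maximum Left-Ventricular Pressure During Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the maximum left-ventricular pressure reached during
    exercise from non-invasive Doppler echocardiographic cardiac output. A
    reduced-order, pressure-driven model of aortic-valve ejection (an
    opening-state ODE coupled to an orifice-inertance flow law) stands in for
    a full fluid-structure simulation of the aortic root, and a regression
    chain maps cardiac output measured by Doppler, Fick-oximetric and
    thermodilution conventions onto ventricular-systolic and aortic-diastolic
    pressure curves versus heart rate. Includes a parametric aortic-root
    geometry, packaged single-subject exercise-test data, and a synthetic
    subject generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    readr,
    deSolve,
    signal,
    pracma,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
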