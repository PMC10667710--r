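Package: exofanova
Title: Functional ANOVA Assessment of Back-Support Exoskeletons in Lifting Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates five biomechanical variables (lumbar compression load,
    trunk angle, trunk angular velocity, trunk angular acceleration, and
    wrist-lumbar horizontal displacement) from lifting-motion time series with
    a nine-segment top-down link-chain inverse-dynamics model, a thin-plate
    spline model of exoskeleton assistive torque as a function of trunk angle
    and angular velocity, and quadratic-programming distribution of trunk
    muscle forces by minimizing summed squared muscle stress. Compares
    with/without-exoskeleton conditions at every normalized time point via
    functional analysis of variance: penalized B-spline smoothing, continuous
    curve registration, and a pointwise F-ratio curve tested against an
    F-criterion. Includes a synthetic lifting-cohort and bench-characterization
    generator so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
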