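Package: runopt3d
Title: Predictive Trajectory Optimization for 3D Running with a
    Musculoskeletal Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implicit-dynamics trajectory optimization for three-dimensional
    running with directional change. A reduced 3D musculoskeletal runner
    (21 degrees of freedom, 18 Hill-type muscle-tendon units, torso torque
    actuators, penetration-based foot-ground contact) is transcribed by
    backward-Euler direct collocation into a sparse nonlinear program and
    solved to predict static standing, track straight running against
    reference gait data, and predict curved running on a circle through a
    rotational periodicity constraint. Includes a synthetic gait-cycle
    reference generator, cycle averaging, and motion-file input/output.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
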