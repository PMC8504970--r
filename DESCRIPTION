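Package: driftcomp
Title: Optimal Compensatory Plasticity Under Synaptic Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how strongly a neural circuit should
    compensate for task-independent synaptic fluctuations in order to
    maintain previously learned function.  Implements the curvature-based
    theory of the optimal compensation-to-fluctuation magnitude ratio on a
    loss landscape (directional Hessian quadratic forms, optimal step
    magnitudes, steady-state ratio predictions), together with simulation
    engines for student-teacher feedforward networks and analytic quadratic
    landscapes, plasticity-rule generators (exact and noise-corrupted
    gradient descent, zero-order probe rules, Newton steps), ratio sweeps,
    and staircase protocols for locating the sweet-spot compensation rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
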