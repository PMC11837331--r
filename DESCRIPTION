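Package: wingclap
Title: Aerodynamics of Flapping-Folding Wings and Ventral Wing-Clap Jets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for two-degree-of-freedom flapping
    wings with active wing folding, inspired by the wing kinematics of
    short-nosed fruit bats. Provides generators for commanded and realized
    flap/fold kinematics (ideal sinusoid or crank-rocker four-bar linkage),
    a quasi-steady blade-element model of instantaneous lift and power
    coefficients, a control-volume estimator of clap-jet lift from
    phase-averaged planar velocity fields (acceleration, momentum-flux and
    pressure terms), and the measurement-processing chain: zero-phase
    Butterworth filtering, mechanism-inertia subtraction via matched
    wings-off trials, normalization to lift and power coefficients,
    Strouhal numbers, phase averaging, and cycle-averaged summaries of
    lift, power and power economy over Strouhal number and fold amplitude.
    A synthetic-data module emulates realized kinematics, force/power
    traces and clap-jet velocity fields with known ground truth so the
    whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
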