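Package: sawstream
Title: Boundary-Driven Acoustic Streaming and Acoustophoresis in SSAW
    Microfluidics
Version: 0.1.0
Authors@R:
    person("sawstream", "maintainers", email = "sawstream@example.org",
           role = c("aut", "cre"))
Description: Device-level simulation of particle and cell separation in
    standing surface acoustic wave (SSAW) and tilted-angle SSAW (taSSAW)
    microfluidic channels. Provides a material library with derived
    acoustic quantities, Bond-matrix tensor rotation for arbitrary
    crystallographic cuts, a partial-wave (Stroh) free-surface solver for
    Rayleigh surface acoustic waves on piezoelectric half-spaces,
    semi-analytic first-order standing-wave fields, the limiting-velocity
    slip boundary condition of Rayleigh-Schlichting boundary-layer
    streaming, a staggered-grid Stokes solver for the second-order
    streaming flow, viscous-corrected acoustic radiation forces, and
    Lagrangian particle tracing with separation metrics, multi-stage
    device presets and tilt-angle optimisation sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
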