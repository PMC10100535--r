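Package: surfhop
Title: Fewest-Switches Surface Hopping on Model Surfaces with QM/MM
    Embedding and Excited-State Lifetime Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory surface hopping for excited-state decay studies on
    analytic multi-state model Hamiltonians. Provides diabatic model
    surfaces with exact gradients and nonadiabatic coupling vectors, a
    surrogate classical solvent bath, Morokuma-style subtractive QM/MM
    energy and gradient combination, velocity-Verlet nuclear propagation
    with an Andersen thermostat restricted to the solvent, explicit
    integration of the electronic amplitude equations with Tully's
    fewest-switches hop criterion and energy-conserving velocity
    rescaling, and swarm population statistics. Excited-state lifetimes
    are obtained by fitting sequential two-step first-order decay kinetics
    to normalized state occupancies, with standard errors estimated by a
    reshuffled-subset 1/N extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
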