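Package: clampsim
Title: Single-Compartment Ion Channel Biophysics Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Conductance-based simulation of a single-compartment membrane
    carrying eleven Hodgkin-Huxley style channel mechanisms (voltage-gated Na,
    delayed-rectifier K, Cl, Na/K leaks, two-component A current, M current,
    calcium-activated KCa and AHP currents, and GHK constant-field CaT/CaL
    calcium currents coupled to an intracellular calcium pool). Simulations run
    under three-segment current-clamp or voltage-clamp protocols, integrated
    with forward Euler (a fourth-order reference integrator is provided for
    verification), and export voltage, current and conductance time series as
    CSV. Includes a command-line front end for running protocols, locating the
    resting potential, listing channels and validating configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    utils,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
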