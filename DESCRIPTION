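Package: obtcell
Title: Oscillation-Based Impedance Monitoring of Cell-Culture Growth and
    Differentiation
Version: 0.1.0
Authors@R:
    person("obtcell", "maintainers", email = "obtcell@example.org",
           role = c("aut", "cre"))
Description: Equivalent-circuit models of cell-covered microelectrodes and
    differentiated tissue, a describing-function (harmonic-balance) solver
    for the oscillation-based test (OBT) condition with an independent
    relay-feedback transient oracle, fill-factor estimation from oscillation
    amplitude, a synthetic-study generator, and a time-series pipeline that
    segments growth/plateau/differentiation phases of electrically monitored
    skeletal-myoblast cultures and derives per-well gap, bulk and tissue
    resistances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
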