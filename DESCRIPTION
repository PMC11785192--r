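Package: cartov
Title: Tumor, CAR T-Cell and Oncolytic Virus Dynamics In Vitro
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled ordinary-differential-equation models of glioblastoma
    cell killing by chimeric antigen receptor (CAR) T-cells and an oncolytic
    virus, as measured by impedance-based cell-index time series. Provides
    the full four-compartment model together with its CAR T (predator-prey)
    and oncolytic-virus (SIR-type) sub-modules, phase-plane analysis of the
    non-dimensionalized sub-modules, a particle-swarm staged calibration
    pipeline for cell-index data, virus burst-size sensitivity analyses,
    infected-cell-fraction analyses, and treatment combination and scheduling
    predictions. A synthetic-data generator emulates the impedance assay
    layout so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
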