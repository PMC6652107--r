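Package: liverregen
Title: Compartmental Modeling of Liver Regeneration After Partial Hepatectomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and calibrates a four-compartment ordinary
    differential equation model of mouse liver regeneration after 70%
    partial hepatectomy. The compartments are hepatocytes, Kupffer cells,
    recruited macrophages, and endothelial cells, expressed as fractions
    of the healthy liver. The package provides fixed-step fourth-order
    Runge-Kutta integration, extraction of simulated measurement curves
    (liver volume, total macrophages, Kupffer cells, angiogenic
    activity), least-squares calibration of the six rate coefficients
    against time-course measurements, a synthetic-cohort generator
    emulating a three-group longitudinal animal study, and a small
    reproducible pipeline layer with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
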