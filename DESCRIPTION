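Package: thermokin
Title: Thermal Degradation Kinetics, Activation Thermodynamics and
    Dose-Response Analysis of Plant Bioactives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits first-order thermal degradation kinetics to time-series of
    plant bioactive responses (total anthocyanins, antioxidant activity) and
    derives half-life and decimal reduction times; estimates Arrhenius
    activation energy and z-values across temperatures; computes Eyring
    activation thermodynamics (enthalpy, Gibbs free energy, entropy) per
    temperature; infers IC50 values from log-linear enzyme-inhibition
    dose-response data with Tukey compact-letter group comparison; and
    provides pH-differential, Folin-Ciocalteu and DPPH spectrophotometric
    quantification helpers. Includes a synthetic-data generator emulating a
    replicated multi-temperature heating design so the whole pipeline is
    testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
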