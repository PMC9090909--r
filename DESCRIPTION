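Package: etakin
Title: Eta-Order Photokinetics and Drug Actinometry under Polychromatic Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form eta-order kinetics for AB(1-Phi) photoreactions whose
    photoproduct absorbs the incident light, under polychromatic irradiation.
    Provides the integrated rate law and its explicit Lambert-W inversion of
    concentration versus time, a reference ODE simulator of the unapproximated
    per-wavelength rate law, spectral data handling with photon-flux unit
    conversion, rate-constant extraction from kinetic traces, the lamp-specific
    drug-actinometry calibration protocol, and synthetic system generators for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
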