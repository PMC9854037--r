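Package: tg43co
Title: TG-43 Dosimetry Toolkit for HDR Cobalt-60 Afterloading Sources
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving and applying AAPM TG-43/TG-43U1 dosimetric
    parameters of encapsulated cylindrical cobalt-60 high-dose-rate
    brachytherapy sources. Includes an analog photon Monte Carlo with a
    collision-kerma track-length estimator (two-line Co-60 spectrum,
    Klein-Nishina Compton scattering, embedded photon mass-coefficient
    tables), extraction of the dose-rate constant, radial dose function,
    2D and 1D anisotropy functions and air-kerma strength, a
    polynomial-times-exponential radial dose function fitter, a forward
    TG-43 dose-rate engine producing along-away quality-assurance tables,
    an uncertainty-budget calculator, and packaged reference tables for the
    GZP3 afterloading system source designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
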