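Package: honeynir
Title: Portable NIR Chemometrics for Honey Quality and Botanical Authentication
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for predicting physicochemical properties
    of honey from portable near-infrared (NIR) spectra and for classifying
    honey botanical type. Implements log(1/R) conversion, scatter correction
    (SNV, MSC, detrend, SNV-detrend) and gap-segment derivatives encoded in
    the 4-digit WinISI-style nomenclature; modified partial least squares
    (MPLS) calibration with Mahalanobis H-statistic spectral outlier screening,
    T-criterion chemical outlier elimination and grouped cross-validation;
    calibration and external-validation statistics (SEC, SECV, RSQ, RPD, SEP,
    SEP(C)); linear discriminant analysis with Wilks' lambda and Bartlett
    chi-square diagnostics; rule-based melissopalynological honey typing; and
    a seeded synthetic honey-spectra generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
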