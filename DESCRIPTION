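Package: dualcsia
Title: Dual-Element Compound-Specific Isotope Analysis of Reductive
    Dechlorination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dual-element (carbon/chlorine) compound-specific
    stable isotope analysis (CSIA) of microbial reductive dechlorination.
    Estimates bulk isotope enrichment factors by Rayleigh regression,
    dual-element slopes (Lambda) relating carbon to chlorine isotope
    fractionation, and apparent kinetic isotope effects (AKIE) under
    alternative mechanistic parameterizations, with Streitwieser-limit
    screening to discriminate concerted from stepwise dihaloelimination.
    Includes a synthetic assay generator reproducing the sacrificial-vial
    design of resting-cell fractionation experiments and an
    isotopologue-resolved forward simulator used as an independent check
    on the position-specific isotope-effect algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
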