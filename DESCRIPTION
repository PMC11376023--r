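Package: isocoder
Title: Isotope Ratio Encoding of Molecular Information in Mass Spectrometric Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for storing and reading molecular information in mixtures of
    deuterium isotopologues. Computes theoretical isotope patterns of arbitrary
    chemical formulas by elemental-distribution convolution, builds unit-mass MS
    fingerprints of component mixtures, scores fingerprint similarity with the
    normalized dot product (NDP), enumerates and audits combinatorial mixture
    code spaces, decodes measured fingerprints back to mixture compositions,
    deconvolutes component isotopologue distributions by non-negative least
    squares, and predicts fingerprints of covalently tagged products. Includes a
    synthetic-data generator for imperfectly deuterated components and noisy
    instrument readouts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
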