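Package: hsqcmult
Title: Automated Multiplet Identification and Decomposition in 2D
    1H,13C-HSQC NMR Tracer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Data-driven identification, assignment and quantification of
    13C-13C scalar-coupling multiplets in processed 2D-1H,13C-HSQC NMR
    spectra from stable-isotope tracing experiments.  Resonances are
    located inside library-centred search windows, overlapping signals are
    unmixed by fixed-point independent component analysis, multiplets are
    identified by combinatorial matching against first-order coupling
    simulations with a shift-distance-adjusted score, and isotopomer
    component fractions are quantified by non-negative least squares with
    a coefficient-of-determination quality score.  Includes readers for
    NMRPipe and Sparky spectra, a portable text grid format, a synthetic
    spectrum generator with ground truth, and JSON/markdown reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ica,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
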