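Package: renalfib
Title: Dynamical Model of Myeloma-Driven Renal Tubulointerstitial Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Power-law (S-system) ordinary differential equation model of
    proximal tubule cell injury caused by monoclonal free light chains in
    multiple myeloma. Implements a three-population healthy-kidney system
    (proximal tubule cells, free light chains, renal fibroblasts) and a
    four-population extension forced by Gompertz tumor growth, together with
    structural enumeration of the healthy system's eight equilibria, linear
    stability classification via the analytic Jacobian, stiff-capable
    trajectory integration with threshold-crossing detection, and canned
    scenario runs (homeostasis perturbation suite, untreated-tumor
    progression).
License: MIT
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
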