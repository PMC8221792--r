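Package: maintflux
Title: Maintenance-Energy Estimation for Constraint-Based Models of CHO Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study non-growth-associated maintenance energy (mATP) in
    genome-scale metabolic models of Chinese hamster ovary (CHO) cells.
    Implements flux balance analysis (FBA) and parsimonious FBA on a
    bounded-variable simplex core, mapping of coarse 13C flux-analysis
    reaction namespaces onto genome-scale models, grid-search estimation of
    mATP by minimizing the median relative flux error, uptake-minimization
    objective functions, chemostat steady-state rate calculations with error
    propagation and carbon-recovery accounting, and experimental-style
    determination of mATP and the maximal ATP yield from ATP-hydrolysis
    maximization across dilution rates. Ships a compartmentalized
    central-carbon toy model with a proton-explicit electron transport chain
    (tunable P/O ratio) and generators for synthetic 13C and chemostat
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
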