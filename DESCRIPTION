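Package: gcreweight
Title: Grand-Canonical Reweighting of Fixed-N Molecular Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-likelihood combination of molecular simulations run at
    different fixed particle numbers into grand-canonical ensemble averages
    that are smooth functions of reagent concentration. Includes an
    exactly-enumerable lattice model used as a ground-truth oracle, geometric
    extraction of probe-RNA binding states from trajectory frames, and a
    downstream analysis of SHAPE probing cooperativity: concentration-dependent
    reactivities, power-law exponents, pairwise free-energy couplings with
    Bayesian-bootstrap uncertainties, and Benjamini-Hochberg significance
    selection. Also normalizes experimental capillary-electrophoresis read
    tables across concentration channels and compares reactivity exponents
    between structural groups.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
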