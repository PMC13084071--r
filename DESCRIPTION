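Package: phytoQSAR
Title: GA-MLR QSAR Modeling, Validation and Binding-Energy Bookkeeping for
    Dual-Target Enzyme Inhibition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: A ligand-based modeling toolkit for dual-target enzyme
    inhibition studies in phytochemical drug discovery. Builds multiple
    linear regression QSAR models on molecular-descriptor matrices with
    genetic-algorithm descriptor selection and Kennard-Stone training-set
    partitioning; computes the full internal/external validation battery
    (leave-one-out Q2, regression-through-origin metrics, rm2 metrics,
    Golbraikh-Tropsha criteria, MAE-based model quality) and the
    leverage-based applicability domain (Williams plot). Also provides
    conceptual-DFT global reactivity descriptors from frontier orbital
    energies, MM-GBSA thermodynamic-cycle validation and component
    aggregation with post-dynamics correlation analysis, pIC50/IC50 unit
    conversion, log-logistic dose-response IC50 fitting, and seeded
    synthetic-data generators for every input class so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
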