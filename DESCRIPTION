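Package: cryoscreen
Title: Few-Shot Quality Screening of Cryo-EM Micrographs
Version: 0.1.0
Authors@R:
    person("cryoscreen", "developers", email = "cryoscreen@example.org",
           role = c("aut", "cre"))
Description: Few-shot quality classification of cryo-electron microscopy
    micrographs. Combines real-space crops with centered log-scaled power
    spectra in a dual-stream embedding network trained with triplet loss and
    online batch-hard mining, classifies new micrographs by k-nearest-neighbour
    voting over crop embeddings, and evaluates with average precision
    normalized by the majority-class proportion (AUPRC Gain). Includes MRC2014
    and single-channel TIFF readers, a seeded synthetic micrograph simulator
    covering the common defect taxonomy (crystalline ice, contamination,
    drift, support film), leakage-free micrograph-level splits, n-shot episode
    sampling, a multi-seed experiment runner and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
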