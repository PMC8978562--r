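Package: criafs
Title: Correlation-Redundancy and Interaction Analysis for Feature
    Selection on Discrete Genomic Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic filter feature selection for discrete
    genomic feature matrices such as GISTIC-coded copy-number calls.
    Implements the CRIA criterion (correlation-redundancy and interaction
    analysis), which combines symmetrical-uncertainty relevance and
    redundancy with a total-correlation (discrete copula entropy)
    interaction factor, together with eleven classical
    information-theoretic comparator criteria (MIFS, mRMR, NMIFS, CMI,
    DWFS, IWFS, RAIW, CFR, JMIM, DCSF, MRI), MDLP discretization of
    continuous features, greedy forward-selection engines, incremental
    feature selection (IFS) accuracy curves under repeated stratified
    cross-validation, classification metrics, and a seeded
    synthetic-data generator with known relevance, redundancy and
    interaction structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    optparse,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
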