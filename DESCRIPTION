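Package: mhonet
Title: Metabolic Health Phenotyping and Partial-Correlation Networks for
    Obesity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying metabolically healthy and unhealthy
    obesity (MHO/MUO) in young-adult cohorts with Gaussian graphical
    models. Scores common measurement instruments (food-frequency
    questionnaires into daily nutrient intakes, the DASS-21
    depression/anxiety/stress scales, IPAQ activity categories),
    classifies participants by modified IDF cardiometabolic criteria
    with an optional HOMA-IR cutoff, compares groups with Mann-Whitney
    U tests under Benjamini-Hochberg control, and estimates sparse
    partial-correlation networks by a graphical lasso with EBIC penalty
    selection, including Rho-band sub-network extraction and
    Fruchterman-Reingold rendering. A Gaussian-copula cohort simulator
    with a known sparse precision matrix provides ground truth so that
    the whole chain, including edge-support recovery, is testable
    without access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
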