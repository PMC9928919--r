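Package: ntabatch
Title: Batch Effect Assessment and Correction for Nontarget LC-HRMS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for processing multi-batch nontarget liquid
    chromatography high-resolution mass spectrometry (LC-HRMS) feature
    tables from long-term environmental monitoring campaigns, with
    wastewater surveillance as the motivating application. Provides
    readers for MS-DIAL style alignment exports, abundance and
    blank-based feature filtering, joining of split features (duplicate
    and alternating alignment artifacts), log2/quantile/internal-standard
    normalization, a from-scratch empirical-Bayes location-scale batch
    correction (parametric and nonparametric priors), principal variance
    component analysis (PVCA) with REML random-intercept models,
    Ward hierarchical clustering with silhouette and gap-statistic
    diagnostics, moderated-t differential abundance with
    Benjamini-Hochberg control, and a synthetic multi-batch data
    generator with recorded ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    lme4,
    cluster
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
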