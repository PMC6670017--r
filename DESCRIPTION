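Package: bonemet
Title: Molecular Subtyping of Prostate Cancer Bone Metastases from
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for discovering and classifying molecular
    subtypes of prostate cancer bone metastases from bulk gene expression
    cohorts. Implements bead-array preprocessing (background-based probe
    filtering, quantile normalization, per-cohort probe centering, probe
    collapse, cross-cohort merging), principal component analysis with
    sevenfold cross-validated component significance, multi-algorithm
    consensus clustering with a grouping-preservation statistic, rank-based
    marker-panel selection, an OPLS-DA subtype classifier with predicted-value
    thresholds, immunoreactivity (IR) scoring with a combinatory PSA/Ki67
    prognostic grouping, cause-specific Kaplan-Meier/Cox survival analysis,
    and hypergeometric gene-set over-representation and network
    over-connectivity tests. A synthetic-cohort generator with planted
    subtypes, batch structure, survival and immunohistochemistry makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    limma,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
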