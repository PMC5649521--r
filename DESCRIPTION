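Package: ipfstrat
Title: Severity Stratification and Signature Discovery for IPF Lung Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised severity stratification of idiopathic pulmonary
    fibrosis (IPF) lung transcriptomes. Patients are clustered on principal
    components of their expression profiles with Ward linkage, the cluster
    count is selected by separation of lung-function measures (FEV1, FVC,
    DLCO), and per-cluster differential expression is computed with an
    empirical-Bayes moderated t-statistic. From the per-cluster gene lists
    the package derives core, cluster-unique and module signatures, validates
    them with sensitivity-calibrated logistic classifiers, prioritizes novel
    candidate genes by rank-product aggregation of functional-similarity and
    fold-change ranks, and searches for a minimal secreted-protein biomarker
    panel. A synthetic-cohort generator with full ground truth makes every
    stage testable without access to the original microarray cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
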