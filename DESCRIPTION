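Package: eaccd
Title: Ensemble Clustering of Censored Survival Cohorts for Prognostic Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-driven prognostic staging systems for cancer registry
    data by clustering cohorts of patients who share the same levels of staging
    factors (TNM, age, histology). Dissimilarity between two cohorts is the
    censoring-aware Mann-Whitney probability that survival in one cohort is
    shorter than in the other, estimated by Kaplan-Meier plug-in; dissimilarities
    are refined by an ensemble of Partitioning Around Medoids runs over varying
    cluster counts, clustered by minimax-linkage agglomeration with per-cluster
    prototypes, and cut into ordered prognostic groups at the knee of the
    Harrell C-index curve. Includes comparison machinery against AJCC
    8th-edition lung staging (contingency tables, midrank Spearman correlation,
    a correlated C-index difference test) and a synthetic SEER-like case-listing
    generator with planted group structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    cluster,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
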