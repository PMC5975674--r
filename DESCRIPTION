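Package: handprint
Title: Multi-Omics Patient Stratification by Similarity Network Fusion and
    Consensus Spectral Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-step pipeline for deriving multi-omics patient subtypes
    ("handprints"): data preparation with an explicit missing-data decision
    procedure (imputation below a missingness threshold, presence/absence
    collapse above it), survival-anchored feature-wise linear-model
    filtering, similarity network fusion of per-platform patient affinity
    matrices followed by subsampled consensus spectral clustering with a
    stability statistic (deviation from ideal stability) and constrained
    selection of the cluster number, and downstream biomarker derivation:
    one-vs-rest differential signatures with Benjamini-Hochberg correction,
    hypergeometric gene-set enrichment, SVM-ranked recursive feature
    elimination feeding a random-forest classifier, and a multi-block sparse
    PLS discriminant model. Includes a synthetic multi-omics cohort
    generator with planted subtypes, cluster-linked censored survival,
    missingness and batch effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
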