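Package: dcisEscore
Title: Single-Cell Phenotyping and Escore Risk Stratification for DCIS
    Multiplexed Immunofluorescence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a single-cell analysis pipeline for
    multiplexed immunofluorescence (MxIF) imaging of ductal carcinoma in situ
    (DCIS): cell-, field-of-view- and patient-level quality control for
    iterative staining data, exposure correction and slide normalisation of
    marker intensities, consensus k-means phenotyping of ER/HER2/cMET/SLC7A5
    with PAC-based selection of the number of clusters, compositional patient
    cluster profiles, a logistic "Escore" that stratifies the risk of a second
    breast cancer event, leave-one-out cross-validation, and Kaplan-Meier /
    log-rank evaluation of the binary risk groups. Because no per-cell data
    were deposited for the original cohort, the package includes a synthetic
    cohort generator that emulates the statistical structure the analysis
    assumes (cluster archetypes, group-conditional patient profiles, slide
    batch effects, exposure-time variation and QC artifacts), so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, Clustering, Classification, Survival, QualityControl
RoxygenNote: 7.3.3
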