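Package: agebend
Title: Age-Position Detection in Cross-Sectional Expression Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects age-regulated RNA expression trends in cross-sectional
    probe-by-sample datasets and locates the chronological ages
    ("age-positions") at which the major trends bend.  The pipeline smooths
    each probe with competing regression models selected by leave-one-out
    cross-validation, filters probes with a quadratic-versus-null F test,
    assesses dataset-level age association with a permutation global test,
    clusters centered trends by k-means under Euclidean or
    absolute-correlation distance, estimates bend ages from the intersection
    of reciprocal trends, and tests the resulting gene lists for gene-set
    over-representation with Fisher's exact test.  A synthetic-data
    generator with known bend structure supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, TimeCourse, Clustering, Regression
RoxygenNote: 7.3.3
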