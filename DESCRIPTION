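Package: mealdtw
Title: Time-Series Clustering of Protein Intake Across Eating Occasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the temporal distribution of dietary protein and
    indispensable amino acid (IAA) intake from timestamped food diaries.
    Builds true-ileal-digestibility-adjusted eating occasions, encodes each
    participant-day as an ordered series of per-occasion protein amounts,
    compares series with length-normalised dynamic time warping, groups them
    by Ward.D2 agglomerative clustering with average-silhouette diagnostics
    and classical multidimensional scaling, and summarises per-cluster protein
    adequacy against per-occasion and daily thresholds with Kruskal-Wallis and
    Dunn post hoc tests. Ships a synthetic vegan-cohort food-diary generator
    for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
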