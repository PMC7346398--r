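Package: fcstrength
Title: Voxel-Wise Functional Connectivity Strength and Imaging-Genetics
    Group Inference for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes voxel-wise functional connectivity strength (FCS,
    a weighted degree-centrality statistic) from resting-state BOLD
    series: nuisance regression with the Friston-24 motion expansion
    plus white-matter, cerebrospinal-fluid and global signals, temporal
    band-pass filtering, Fisher r-to-z thresholded whole-mask
    correlation sums, and Gaussian smoothing. Provides voxel-wise
    genotype-group inference under additive, dominant and recessive
    genetic models with Gaussian-random-field cluster-level correction,
    Fisher LSD post hoc comparisons, Hardy-Weinberg and contingency
    chi-square tests, one-way ANOVA from raw data or printed summary
    moments, and genotype-stratified Spearman brain-behavior
    correlations. Includes a seeded synthetic-cohort generator (BOLD
    runs with a genotype-dosed connectivity hub, motion traces,
    phenotypes) with ground truth for parameter-recovery testing, and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
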