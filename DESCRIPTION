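Package: sensmap
Title: Distance-Based Analysis of Napping Sensory Data with MFA and QDA
    Panel Statistics
Version: 0.1.0
Authors@R:
    person("sensmap", "maintainers", email = "maintainers@sensmap.invalid",
           role = c("aut", "cre"))
Description: Tools for the statistical analysis of rapid descriptive sensory
    data.  Napping (projective mapping) placements are turned into per-rater,
    panel-averaged, and concatenated-space product distance matrices, which
    feed average-linkage (UPGMA) hierarchical clustering, free-text descriptor
    profiling of the clusters, and exact (Freeman-Halton) association tests of
    cluster membership against product design factors such as breed and
    feeding group.  A from-scratch Multiple Factor Analysis with
    rater-resampling bootstrap confidence ellipses and projection-distortion
    diagnostics is provided for comparison, together with the companion
    quantitative descriptive analysis (QDA) panel statistics: panel-averaged
    ANOVA per attribute, pairwise comparisons with confidence intervals,
    subject-effects models, and a p-value ECDF uniformity diagnostic.  Seeded
    generators simulate Napping and QDA panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
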