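Package: d50vbm
Title: D50 Disease-Progression Modelling and Voxel-Based Morphometry for ALS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the sigmoidal D50 disease-progression model to longitudinal
    ALSFRS-R series of patients with amyotrophic lateral sclerosis and derives
    the model descriptors (D50, rD50, cFS, cFL, phase, aggressiveness class).
    Provides cohort staging tables, a synthetic-cohort and synthetic tissue
    density volume generator, and a voxel-wise morphometry statistics engine:
    ANCOVA-style general linear model contrasts with nuisance covariates,
    threshold-free cluster enhancement (TFCE), max-statistic permutation
    family-wise error correction with Freedman-Lane residual permutation,
    Bonferroni-adjusted masked regressions and cluster reporting, plus
    end-to-end analysis presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
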