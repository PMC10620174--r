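Package: cloudharmony
Title: Dual-Factor Harmonization of Multi-Lesion Radiomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes lesion-level radiomic feature tables collected across
    several centers and scanners. Implements a dual adversarial deconfounding
    autoencoder that embeds lesions into a low-dimensional space while two
    adversarial classification heads unlearn the center and scanner labels;
    location/scale ComBat with parametric empirical-Bayes shrinkage together
    with its ridge-regularized variant and sequential two-factor cascades; a
    rank-based Point Cloud Semantic Drift statistic with a Gaussian-noise
    empirical null to test whether a transformation preserves the shape of
    each patient's lesion cloud; patient-level cloud representations and
    repeated-split Cox concordance evaluation; and a synthetic cohort
    generator with nested center/scanner batch effects and
    heterogeneity-linked survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
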