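Package: psoasvol
Title: Automated Iliopsoas Muscle Volumetry from Dixon MRI
Version: 0.1.0
Authors@R:
    person("psoasvol", "maintainers", email = "maintainers@psoasvol.org",
           role = c("aut", "cre"))
Description: Fully automated measurement of iliopsoas muscle volume from
    water-signal Dixon MRI. Implements landmark-anchored cropping,
    percentile intensity normalization, reflection and random affine
    augmentation, a 3D residual encoder-decoder segmentation network with
    SELU activations trained with a soft Dice loss, k-fold cross-validation
    with Dice and Bland-Altman agreement reporting, per-subject volumetrics
    (left/right/total volume, left-right asymmetry, iliopsoas muscle index)
    with quality-control screening, and population statistics (rank
    correlations, Wilcoxon tests, spline age trends). A phantom simulator
    generates Dixon-like volumes with ground-truth masks, hip landmarks and
    demographic cohorts so the whole pipeline can be exercised and tested
    without access to cohort imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
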