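Package: qdabiplot
Title: Quadratic Discriminant Analysis Biplots with Classification Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Visualisation of quadratic discriminant analysis (QDA) in two
    dimensions. Per-class quadratic discriminant scores (squared Mahalanobis
    distance under the class covariance plus its log-determinant) are
    standardized into a score matrix whose principal components give a 2-D
    display of the samples; classification regions are rendered by
    back-projecting every display point to the per-class scores and applying
    the discriminant rule, and the original variables are added as calibrated
    regression axes with orthogonal parallel translation. The classical
    canonical variate analysis (CVA/LDA) biplot that the display generalizes
    is also provided, together with a multivariate-normal and binary
    presence/absence data simulator for three-group benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
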