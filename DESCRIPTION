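Package: stagenet
Title: Stage-Wise Sparse Metabolite Networks from Longitudinal Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples principal-component analysis over sequential cell-stage
    pairs with graphical-lasso sparse precision estimation to expose
    stage-specific metabolic subnetworks in longitudinal metabolomics data.
    Provides a from-scratch blockwise coordinate-descent graphical lasso with
    cross-validated penalty selection, transition-pair PCA with a
    discriminant-component selector, partial-correlation network extraction
    with overlay annotation (stage assignment, loading intensity,
    concentration change), template-pattern correlation screening across
    ordered stages, and a synthetic-data generator with planted precision
    structure and stage markers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
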