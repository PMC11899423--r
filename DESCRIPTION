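Package: cldaboost
Title: Common-Vectors LDA and AdaBoost Ensembles for Near-Infrared
    Spectral Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of high-dimensional, small-sample spectral data
    (e.g. near-infrared absorbance spectra used for geographical-origin
    authentication of foods). Implements common-vectors linear discriminant
    analysis (CLDA), which extracts discriminative common vectors from the
    null space of the within-class scatter matrix and therefore remains
    well-defined when the channel count exceeds the sample count, and an
    AdaBoost.M1 ensemble of CLDA subspaces with nearest-neighbour weak
    classifiers. Also provides spectral preprocessing (Savitzky-Golay
    smoothing, multiplicative scatter correction, standard normal variate),
    a PCA + Fisher LDA baseline, K-nearest-neighbour and Gaussian naive
    Bayes back-end classifiers, stratified train/test splitting, a synthetic
    spectra generator for method evaluation, and experiment/grid runners
    that return tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
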