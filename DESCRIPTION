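Package: nirleaf
Title: Maturity Discrimination of Leaf Tissue from NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometrics toolkit for classifying the maturity level of
    fresh plant leaves from near-infrared (NIR) reflectance spectra.
    Provides readers and writers for wide-format spectral tables on a
    regular wavelength grid, the classical pretreatment operators
    (Savitzky-Golay smoothing and derivatives, standard normal variate,
    multiplicative scatter correction, min-max normalisation) with pipeline
    composition and PCA scores, deterministic Kennard-Stone train/test
    partitioning, five interchangeable classifiers (a one-dimensional
    convolutional neural network trained by backpropagation, an extreme
    learning machine, inverse-distance-weighted k-nearest neighbours, a
    single-hidden-layer backpropagation network, and an RBF support vector
    machine), the NER discriminant-accuracy statistic with repeated-run
    aggregation, pretreatment-comparison and hyperparameter-tuning
    protocols, and a seeded generator of synthetic five-class maturity
    spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
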