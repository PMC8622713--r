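Package: ftirstrat
Title: FTIR Imaging Chemometrics for Oral Epithelial Lesion Classification
    and Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for discriminating oral squamous cell
    carcinoma from hyperkeratosis in FTIR hyperspectral tissue images and
    for stratifying oral epithelial dysplasia samples by spectral
    similarity. Provides a seeded synthetic-cohort generator with known
    ground truth, the standard chemometric preprocessing chain
    (absorbance conversion, fingerprint selection, Savitzky-Golay
    smoothing, extended multiplicative signal correction, automated
    weighted least-squares baseline correction, vector normalization,
    second-derivative spectra), PCA-based pixel quality control with
    reduced Hotelling T2 / Q-residual outlier removal, hierarchical
    clustering of epithelium versus stroma, representative-spectrum
    selection, a bespoke NIPALS PLS1 discriminant model with grouped
    venetian-blinds cross-validation, loading-based feature-band
    extraction, and side-of-discrimination-line grading of dysplasia
    samples into HK-grade, OSCC-grade, or borderline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    e1071,
    xgboost,
    pROC
Config/testthat/edition: 3
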