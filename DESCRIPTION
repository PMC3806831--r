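Package: plaqopt
Title: Objective MR Protocol Optimization for Carotid Soft-Plaque Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to optimize a multi-contrast carotid vessel-wall MR
    protocol for automated soft-plaque segmentation. Wall pixels from
    aligned multi-contrast slices are classified as soft plaque (lipid-rich
    necrotic core and/or intraplaque hemorrhage) or not, using Gaussian
    scale-space features and a Mahalanobis-distance classifier trained with
    leave-one-out cross-validation at the patient level. Every non-empty
    subset of contrast weightings is evaluated by the Pearson correlation of
    per-patient soft-plaque volume against a reference standard together
    with the total scan duration of the pulse sequences the subset requires,
    exposing the trade-off between protocol length and segmentation
    performance. A seeded synthetic phantom cohort generator reproduces the
    geometric and statistical structure the method assumes, so the full
    pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
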