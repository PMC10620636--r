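Package: rilab
Title: Reference Intervals from Routine Clinical Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate-stratified reference-interval estimation from routine
    clinical laboratory measurements. Implements the direct nonparametric
    percentile method and three indirect methods that isolate the
    physiological component of a mixed hospital population (robust Box-Cox
    quantile estimation with Tukey biweight statistics, iterative
    truncated-Gaussian trimming, and an automated Bhattacharya decomposition
    of binned counts), with 3-sigma outlier screening, percentile-bootstrap
    confidence intervals for the interval limits, and a minimum-sample-size
    gate. A federated path estimates intervals across sites by exchanging
    only uniform-width binned frequency tables, with optional count
    obfuscation, so raw patient-level values never cross a site boundary.
    Includes a seeded generator of multi-site synthetic laboratory cohorts
    with physiological/pathological mixtures, covariate effects and
    diagnosis-linked pathology for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
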