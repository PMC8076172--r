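Package: twinchol
Title: Bivariate Cholesky Twin Modelling of Longitudinal Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of twin phenotypes measured at two
    occasions. Fits bivariate Cholesky ACE/AE/CE/E models by full-information
    maximum likelihood over monozygotic and dizygotic pair covariances,
    accommodating missing observations and singletons; runs the standard
    nested likelihood-ratio model ladder and multigroup homogeneity tests;
    derives visit-specific heritabilities, novel (occasion-specific)
    heritability, genetic/environmental/phenotypic cross-visit correlations,
    difference-score variance decompositions, and profile-likelihood
    confidence intervals. Includes a synthetic twin-cohort generator with a
    packaged reference configuration emulating a two-visit, bi-ethnic youth
    cohort with an AE covariance structure, so the whole pipeline is testable
    without access to raw cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
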