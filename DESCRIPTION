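Package: methage
Title: DNA Methylation Age Prediction with Support Vector Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building DNA methylation based age
    predictors from blood: genome-scale scanning of beta values for
    age-associated CpG sites (detection-p masking, KNN imputation, per-site
    linear regression with Benjamini-Hochberg FDR, CpG-island enrichment),
    calibration and quality control of mass-spectrometric (EpiTYPER-style)
    methylation calls against methylation standards, four competing
    regression families (multivariate linear, quadratic, back-propagation
    neural network, and an epsilon-support-vector regression with RBF kernel
    solved by sequential minimal optimisation), and exhaustive leave-one-out
    subset selection of CpG sites minimising the mean absolute deviation
    from chronological age. Includes a synthetic-methylome generator that
    reproduces the statistical structure of twin discovery cohorts and
    adult validation cohorts so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
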