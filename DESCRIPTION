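Package: ctbayes
Title: Triplicate Quality Control and Bayesian Delta-Ct Classification of
    RT-qPCR Expression Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying tumor samples from TaqMan RT-qPCR threshold
    cycle (Ct) measurements run in technical triplicates. Implements
    chi-square/t-test quality control of replicate triplicates, linear
    delta-Ct expression scores (including the U6-normalized miR375-3p score
    and the weighted miR205-5p/miR21-5p score), a two-class Bayesian
    classifier with Gaussian class-conditional densities and posterior-odds
    decision thresholds, and the associated evaluation statistics (confusion
    tables, accuracy/sensitivity/specificity, ROC/AUC, between-class t-tests,
    stage ANOVA, normalizer stability). A synthetic-cohort generator draws
    Ct triplicates with the class-conditional Gaussian structure the
    classifier assumes, so the whole pipeline is testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
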