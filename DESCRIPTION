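Package: fevcrash
Title: Injury Severity Modelling for Farm Equipment Vehicle Crashes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the injury severity of crashes involving
    farm equipment vehicles (tractors, harvesters and similar machinery) in
    mixed traffic.  Implements a random-parameters ordered logit model with
    heterogeneity in the mean of the random coefficient, estimated by
    simulated maximum likelihood over scrambled Halton draws, together with
    a linear Crammer-Singer multi-class support vector machine benchmark.
    Includes a synthetic crash-record generator that reproduces the marginal
    structure of a confidential national crash registry, preprocessing
    utilities (pavement-condition classification, design encoding,
    correlation screening, train/test splitting, descriptive tables), and
    one-vs-rest ROC/AUC evaluation with permutation importance and partial
    dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    MASS,
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
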