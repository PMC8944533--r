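Package: parlourscore
Title: Evaluating In-Parlour Lameness Scoring Against Locomotion Scoring in Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating checklist-based in-parlour scoring (IPS) of
    dairy cows as a screening alternative to gait-based locomotion scoring (LS)
    in pasture-based herds. Provides a seeded synthetic herd generator with a
    latent-threshold model for class-conditional correlated binary lameness
    indicators; record pairing and composite indicator-count classification;
    diagnostic 2x2 statistics with Clopper-Pearson and standard-logit confidence
    intervals plus Phi-coefficient association screening; a from-scratch
    Gini-impurity decision-tree classifier with size and impurity-decrease
    pruning and stratified 4-fold cross-validation; and confusion-matrix
    reporting with per-class true-positive rate, false-positive rate and
    precision.
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
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
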