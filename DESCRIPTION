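Package: gazeref
Title: Evaluation Measures and Reference Frames for Models of Fixation Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating salience-map models of human fixation
    selection against eye-tracking data. Implements the common evaluation
    measures (AUC with an efficient exact tie-handling algorithm, NSS,
    chance-adjusted salience, ratio of medians, percentile measure, naive
    Bayes percent correct, KL divergence and map correlation), a theoretical
    upper bound on AUC for probabilistic predictions, small-sample corrected
    entropy and KL estimation (Chao-Shen, Jeffreys, Miller-Madow), and a
    cross-validated reference frame of lower (spatial bias) and upper
    (inter-subject consistency) bounds, including subject-specific and
    PCA-cleaned bias predictions. A synthetic fixation generator with
    analytic ground-truth densities makes every stage testable without an
    eye-tracking lab.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
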