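Package: hazardnet
Title: Neural Discrete-Time and Piecewise-Constant Hazard Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-to-event prediction with neural networks built on the
    discrete-time survival likelihood. Implements the Logistic-Hazard
    (discrete hazard with a sigmoid link), PMF (softmax with a fixed tail
    logit), and PC-Hazard (continuous-time piecewise-constant hazard with a
    softplus link) methods, together with equidistant and Kaplan-Meier
    quantile time discretization, constant-density and constant-hazard
    interpolation of discrete survival curves, evaluation statistics
    (true-survival mean squared error, time-dependent concordance, and the
    IPCW integrated Brier score), and a logit-hazard mixture simulator with
    known true survival functions. Networks are multilayer perceptrons with
    ReLU activations, optional batch normalization and dropout, trained by
    Adam with validation-loss early stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    readr,
    optparse
Config/testthat/edition: 3
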