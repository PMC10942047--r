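Package: readerprob
Title: Bayesian Posterior Modelling of Variable Reader Findings and
    Classifier-Output Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models two-stage physician annotations of low-salience imaging
    findings as Bernoulli reads with a latent per-subject positive
    probability, derives the closed-form Bayesian posterior of that
    probability for each of the six first/second-stage outcome groups, and
    calibrates classifier logits onto the posterior logit distributions by
    fitting a single scale parameter per finding. Includes a synthetic-data
    generator (subjects, reader calls, logits, toy grayscale images), a
    small trainable convolutional classifier with cross-validated training,
    standard classification metrics, Grad-CAM saliency, group-wise
    correlation evaluation, and Cohen's kappa agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
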