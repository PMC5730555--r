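Package: equivnoise
Title: Equivalent-Noise Analysis with the Perceptual Template Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for equivalent-noise psychophysics built around the
    Perceptual Template Model (PTM). Simulates trial-level two-alternative
    forced-choice orientation-discrimination studies from PTM observers,
    estimates contrast thresholds per external-noise level by Bayesian
    Weibull fitting, fits the group-coefficient PTM to
    threshold-versus-noise data with nested-model selection, fits a
    trial-level hierarchical Bayesian PTM with group-level population
    distributions, and provides downstream inference: credible-interval
    group comparisons, JZS default Bayes factors, and regression of symptom
    severity on noise parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
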