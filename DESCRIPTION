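Package: taafgex
Title: Transformative Adaptive Activation Functions for Landmark-Based
    Gene Expression Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for inferring genome-wide expression profiles from a
    small set of landmark genes with feed-forward regression networks whose
    neurons use transformative adaptive activation functions (TAAFs): each
    unit wraps a fixed inner activation f in four trainable parameters,
    g(y) = alpha * f(beta * y + gamma) + delta.  Implements the D-GEX-style
    architecture family with per-gene half-networks, Nadam training with
    best-epoch selection, global (whole-matrix) standardization, random and
    series-grouped leak-free data splitting, bootstrap model-comparison
    statistics (MMAE, MMDAE, paired tests), per-gene expert ensembles, a
    seeded synthetic landmark-to-target expression generator, and an
    evaluation of the downstream impact of inference accuracy on
    differential-expression calling.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
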