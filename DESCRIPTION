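Package: lucck
Title: Learning Using Concave and Convex Kernels
Version: 1.0.0
Authors@R:
    person("Sam", "Keller", email = "skeller@example.org",
           role = c("aut", "cre"))
Description: Instance-based supervised classification with per-feature
    heavy-tailed (Cauchy-like) similarity kernels whose exponents are
    learned from the data, so that discriminative features are weighted
    up and noisy ones down (the LUCCK method). Includes linear-programming
    class reweighting for imbalanced problems, generic statistical and
    spectral feature extraction from uniformly sampled signal windows,
    a synthetic tabular data generator with heavy-tailed noise and
    sporadic single-feature corruption, group-aware cross-validation
    with random undersampling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
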