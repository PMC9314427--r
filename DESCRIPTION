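Package: stabcast
Title: Cascaded Gaussian Process Prediction of Metal-Ligand Stability Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting overall stability constants (log beta_n) of
    metal-ligand complexes in aqueous solution. Provides curation of
    stability-constant records (exclusion rules, condition-priority duplicate
    resolution), element-level cation features and SMILES-derived ligand
    descriptors with degeneracy, correlation and variance-inflation-factor
    pruning, exact Gaussian process regression with an automatic relevance
    determination Matern-3/2 kernel, Kullback-Leibler divergence sensitivity
    analysis for feature ranking and feature-count optimization, a two-stage
    cascade in which the predicted first stability constant and its
    uncertainty feed the multi-order model, and a synthetic-data generator
    with planted feature relevance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
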