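Package: metfa
Title: Factor Analytic Mixed Models for Multi-Environment Variety Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Two-stage weighted analysis of multi-environment crop variety
    trial (MET) data.  Stage one reduces each field trial to variety means
    and statistical weights; stage two fits a weighted linear mixed model
    to the combined means by residual maximum likelihood (REML) under a
    family of between-environment genetic variance structures (diagonal,
    compound symmetric, partitioned variance components, factor analytic
    of any order, unstructured).  The package provides empirical BLUPs of
    variety-by-environment effects with prediction error variances,
    principal-component rotation of factor analytic solutions, latent
    regression stability analysis, model-order selection by percentage of
    genetic variance accounted for, dendrogram-ordered genetic correlation
    heatmaps, grower-facing environment and regional prediction tables,
    and a synthetic data generator that emulates national variety testing
    programs (staggered variety entry and retirement, heterogeneous trial
    error variances) so the whole pipeline can be exercised with known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
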