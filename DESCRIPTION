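Package: spinachshelf
Title: Shelf-Life Kinetics, Regional Concentration Models, and Isolate
    Taxonomy for Packaged Leafy Greens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal microbiological quality studies of
    packaged leafy greens such as baby spinach. Fits no-lag primary growth
    models (Baranyi and Buchanan without lag) to shelf-life plate counts,
    selects among them by AIC, and analytically inverts fitted curves for the
    time to a spoilage threshold. Models log10 bacterial concentration against
    growing region with fixed- and mixed-effects regressions, including an
    interaction screen, protected backward elimination, and a preharvest
    weather covariate-selection harness (windowed weather features, variable
    clustering, AIC preselection, correlation replacement, forward selection).
    Provides a resampling-based post hoc power analysis over a grid of
    per-region sample sizes, and post-processes BLAST tabular output into
    genus-level isolate calls with rank escalation, rare-genus pooling,
    Bray-Curtis dissimilarities, principal coordinates analysis, PERMANOVA and
    Monte-Carlo Fisher tests. A seeded synthetic-data generator reproduces the
    statistical structure of a two-region sampling design so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
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
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
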