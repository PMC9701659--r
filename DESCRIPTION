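Package: ecometab
Title: Ecological Analysis of Untargeted Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats untargeted LC-MS feature tables (m/z_rt ion "species" by
    sample) as ecological communities and runs a four-step workflow:
    (i) chemodiversity analysis with species accumulation curves, Chao and
    jackknife richness estimators, rarefaction, rank-abundance model fitting
    with AIC selection, and Shannon/inverse-Simpson/Pielou indices with
    bootstrap confidence intervals; (ii) chemometric screening with
    normalization, principal component analysis, correlation matrices and
    hierarchical clustering; (iii) differential-marker screening by
    fold-change with cross-comparison frequency consolidation; and
    (iv) annotation by molecular-formula/adduct monoisotopic-mass matching at
    ppm tolerance with hypergeometric and permutation pathway enrichment.
    Includes a synthetic-data generator that emulates nutrient-stress
    experiments with known ground truth.
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
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
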