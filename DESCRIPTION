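Package: qppdiallel
Title: Diallel Combining-Ability, Ranking and Protein-Quality Analytics for
    Quality Protein Popcorn Hybrid Trials
Version: 0.1.0
Authors@R: person("QPP", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for factorial (diallel) popcorn hybrid field
    trials grown in generalized complete block designs across locations.
    Provides Type II sums-of-squares ANOVA with variance components solved
    from expected mean squares, broad-sense heritability and genetic
    repeatability, maternal/paternal general combining ability and specific
    combining ability with standard errors, a weighted rank-summation hybrid
    selection index with per-trait decomposition, pedigree-based heterosis
    categorization with Tukey HSD trend testing, phenotypic correlation and
    standardized path coefficients, and amino-acid protein-quality analytics
    (fold change, lysine share of protein, popping loss/retention, inheritance
    mode classification, dietary requirement fractions). Includes a
    multi-trait diallel trial simulator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
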