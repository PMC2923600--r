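Package: geoaims
Title: Geographic Ancestry Inference from Small Panels of PCA-Informative Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects small panels of ancestry-informative SNPs by ranking markers
    on their leverage scores against the top principal components of a genotype
    matrix (PCA-informative markers, PCAIMs), removes redundant markers by greedy
    pairwise-correlation pruning, and predicts the geographic coordinates of
    origin of unlabeled samples by averaging the coordinates of their nearest
    training neighbors in top-2 principal-component space. Provides rigorous
    leave-one-out cross-validation with per-split panel re-selection, external
    test-set validation, per-population error reporting, and a spatial
    allele-frequency cline simulator for evaluating the whole pipeline on
    cohorts with known geographic structure.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
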