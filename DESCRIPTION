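Package: finet
Title: Driver Gene Identification from Functional Impact Scores with a
    Parametric Background Model
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies cancer driver genes from somatic mutation cohorts by
    comparing each gene's observed functional impact score (FIS) against a
    parametric background. Per-mutation FISs (MutationAssessor-style lookup
    tables) are aggregated to gene level, a single-hidden-layer feed-forward
    neural network regresses gene FIS on twelve multi-omics covariates, genes
    are grouped by Ward hierarchical clustering in covariate space, a
    truncated gamma null is fitted to the estimated FISs within each cluster,
    and genes whose observed FIS exceeds the cluster null at Benjamini-
    Hochberg q <= 0.05 are reported as drivers. Includes MAF input/output,
    K-nearest-neighbour imputation of missing covariates, a seeded synthetic
    cohort generator for validation, evaluation metrics (patient coverage,
    deleterious-mutation ratio, overlap precision), and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
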