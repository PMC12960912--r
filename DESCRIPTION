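Package: mmgwas
Title: Matrix-Free Mixed-Model Genome-Wide Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits logistic and gaussian mixed models for genome-wide
    association studies without ever materializing the genetic relationship
    matrix (GRM). The GRM enters only through matrix-vector products with the
    standardized genotype matrix inside a diagonally preconditioned conjugate
    gradient solver; the variance component is estimated by average-information
    REML interleaved with penalized quasi-likelihood iterations. Per-variant
    score tests are calibrated by a variance ratio, corrected by a saddlepoint
    approximation under extreme case-control imbalance, and optionally
    complemented by Firth penalized effect estimates. Includes a
    column-partitioned GRM operator mirroring distributed deployments, a GPU
    capacity planner, manifest-driven multi-trait batching, and a synthetic
    cohort generator with family-structured relatedness for calibration and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
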