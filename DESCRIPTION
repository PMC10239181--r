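Package: dmrsmooth
Title: Regional Differential Methylation from WGBS Counts via Penalized
    Smooth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects differentially methylated regions (DMRs) from
    whole-genome bisulfite sequencing count tables. Implements
    strand-aware concordance filtering and CpG-region partitioning, a
    single-stage regional model with penalized spline covariate-effect
    curves on the logit scale over an over-dispersed binomial read-count
    likelihood (with a region-level Wald test of the disease curve), a
    two-stage bump-style baseline with permutation false-discovery
    q-values, structural gene annotation of DMRs, and cross-method
    overlap and rank-concordance comparison. Includes a synthetic-data
    generator with known smooth effect curves so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    splines,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
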