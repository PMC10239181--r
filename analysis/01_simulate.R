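#!/usr/bin/env Rscript
# Stage 1: generate the synthetic WGBS study.
#
# 9 systemic-sclerosis-like cases vs 4 controls, strand-resolved cytosine
# counts at ~36x merged depth with beta-binomial over-dispersion, 5%
# missing strand records, and known smooth logit-scale effect curves: two
# of six dense CpG regions carry disease effects (one hypomethylated, one
# hypermethylated in cases), everything else is null. A toy gene-feature
# annotation consistent with the simulated coordinates is written
# alongside, as is the ground truth for later recovery checks.

suppressMessages(library(dmrsmooth))
seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  seed = seed,
  chrom_layout = list(
    list(chrom = "chr1", cpgs = c(260L, 260L, 260L, 40L),
         spacing = c(2L, 12L), gap = 500L),
    list(chrom = "chr2", cpgs = c(260L, 260L, 30L),
         spacing = c(2L, 12L), gap = 500L)))
pos <- simulate_positions(cfg)
meta <- simulate_metadata(cfg)

u <- numeric(nrow(pos))
for (rg in unique(pos$region)) {
  idx <- which(pos$region == rg)
  p <- pos$pos[idx]
  u[idx] <- (p - p[1]) / max(p[length(p)] - p[1], 1L)
}
b1 <- numeric(nrow(pos))
b1[pos$region == "chr1_r1"] <- smooth_bump(-2, width = 0.25)(u[pos$region == "chr1_r1"])
b1[pos$region == "chr2_r2"] <- smooth_bump(2, width = 0.25)(u[pos$region == "chr2_r2"])
eff <- make_true_effects(pos, beta0 = 0.4, beta_disease = b1, beta_age = 0.004)

counts <- simulate_counts(pos, meta, eff, cfg)
write_counts(counts, "results/data/counts.tsv")
write_sample_meta(meta, "results/data/meta.tsv")
write_features(toy_features(pos, antisense_regions = "chr1_r1"),
               "results/data/features.bed")
write_effects(eff, "results/data/truth_effects.tsv")

cat(sprintf("simulated %d CpGs in %d intended regions, %d strand records\n",
            nrow(pos), length(unique(pos$region)), nrow(counts)))
cat("effect regions: chr1_r1 (hypo in cases), chr2_r2 (hyper in cases)\n")
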