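# Shared fixtures for the suite: a standard 9-vs-4 design, a standard
# 60-CpG region geometry, and a hand-constructible minimal region_fit.

std_design <- function(seed = 101) {
  set.seed(seed)
  data.frame(disease = rep(c(1, 0), c(9, 4)), age = runif(13, 20, 80))
}

std_positions <- function(n = 60, by = 30) seq(1000, by = by, length.out = n)

# A minimal region_fit with prescribed curves, for functions that only
# read curve values (fitted_group_proportions, pointwise_intervals,
# direction_summary).
fake_fit <- function(pos, beta0, beta1, se1, beta2 = 0, age_center = 50) {
  n <- length(pos)
  curves <- data.table::data.table(
    pos = pos,
    beta0 = rep_len(beta0, n), se_beta0 = 0.1,
    beta1 = rep_len(beta1, n), se_beta1 = rep_len(se1, n),
    beta2 = rep_len(beta2, n), se_beta2 = 0.01)
  structure(list(region_id = "fake", positions = pos, curves = curves,
                 has_age = TRUE, age_center = age_center, converged = TRUE),
            class = "region_fit")
}

# Strand-count rows in the table layout the preprocess stage expects.
strand_row <- function(chrom, pos, strand, sample_id, meth, total) {
  data.table::data.table(chrom = chrom, pos = pos, strand = strand,
                         sample_id = sample_id, meth = meth, total = total)
}
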