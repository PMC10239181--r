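test_that("region overlap counts shared CpGs and is symmetric", {
  a <- data.table::data.table(chrom = "chr1", pos = c(1L, 5L, 9L, 100L),
                              region_id = c("a1", "a1", "a1", "a2"))
  b <- data.table::data.table(chrom = "chr1", pos = c(5L, 9L, 300L),
                              region_id = c("b1", "b1", "b2"))
  ov <- overlap_regions(a, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$n_shared_cpgs, 2L)
  # disjoint sets produce an empty table
  expect_equal(nrow(overlap_regions(a, data.table::data.table(
    chrom = "chr9", pos = 1L, region_id = "z"))), 0L)
  # identical partitions: one pair per region, full size
  self <- overlap_regions(a, a)
  expect_equal(nrow(self), 2L)
  expect_equal(sort(self$n_shared_cpgs), c(1L, 3L))
  # duplicate CpG within a region is refused
  dup <- rbind(a, a[1])
  expect_error(overlap_regions(dup, b), "duplicate")
})

test_that("overlap agrees with a brute-force set-intersection oracle", {
  set.seed(61)
  for (rep in 1:10) {
    pos_pool <- sample(1:2000, 400)
    mk_part <- function(n_regions) {
      pos <- sort(sample(pos_pool, sample(50:200, 1)))
      data.table::data.table(chrom = "chr1", pos = pos,
                             region_id = sprintf("r%02d",
                                                 sort(sample(seq_len(n_regions),
                                                             length(pos), TRUE))))
    }
    a <- mk_part(8); b <- mk_part(8)
    ov <- overlap_regions(a, b)
    # brute force over all region pairs
    for (ra in unique(a$region_id)) for (rb in unique(b$region_id)) {
      shared <- length(intersect(a$pos[a$region_id == ra],
                                 b$pos[b$region_id == rb]))
      hit <- ov[ov$region_id_a == ra & ov$region_id_b == rb, ]
      if (shared > 0) expect_equal(hit$n_shared_cpgs, shared)
      else expect_equal(nrow(hit), 0L)
    }
    # symmetry up to transposition
    ov_t <- overlap_regions(b, a)
    m1 <- ov[order(region_id_a, region_id_b),
             .(x = region_id_a, y = region_id_b, n = n_shared_cpgs)]
    m2 <- ov_t[order(region_id_b, region_id_a),
               .(x = region_id_b, y = region_id_a, n = n_shared_cpgs)]
    expect_equal(m1, m2)
  }
})

test_that("significance ranking breaks ties by genomic order", {
  res <- data.table::data.table(chrom = "chr1", start = c(10L, 40L, 20L),
                                pvalue = c(0.01, 0.001, 0.5))
  expect_equal(rank_by_significance(res)$rank[order(res$pvalue)], 1:3)
  tied <- data.table::data.table(chrom = c("chr2", "chr1", "chr1"),
                                 start = c(5L, 50L, 10L),
                                 pvalue = 0.2)
  r <- rank_by_significance(tied)
  expect_equal(r[r$chrom == "chr1" & r$start == 10L, ]$rank, 1L)
  expect_equal(r[r$chrom == "chr2", ]$rank, 3L)
  # missing values are excluded with a warning
  expect_warning(rank_by_significance(
    data.table::data.table(chrom = "chr1", start = 1:2,
                           pvalue = c(NA, 0.1))), "excluded")
})

test_that("the cumulative average rank curve matches hand enumeration", {
  # single matched gene at rank 1 of M: curve value 1
  g1 <- data.table::data.table(gene_id = "A", min_pvalue = 0.001)
  r2 <- stats::setNames(1L, "A")
  expect_equal(cumulative_average_rank(g1, c(r2, B = 2L))$curve$running_mean,
               (2 - 1 + 1) / 2)
  one <- cumulative_average_rank(g1, stats::setNames(1L, "A"))
  expect_equal(one$curve$running_mean, 1)
  # no matches: empty curve
  none <- cumulative_average_rank(g1, stats::setNames(1L, "Z"))
  expect_equal(nrow(none$curve), 0L)
  expect_true(is.na(none$argmax_gene))
  expect_error(cumulative_average_rank(g1[0], r2), "empty")

  # 5-gene worked example, M = 4 ranked genes in method 2
  genes <- data.table::data.table(
    gene_id = c("a", "b", "c", "d", "e"),
    min_pvalue = c(0.001, 0.003, 0.01, 0.02, 0.04))
  ranks <- stats::setNames(c(2L, 1L, 4L, 3L), c("a", "c", "d", "x"))
  res <- cumulative_average_rank(genes, ranks)
  # matched walk: a (rank 2 -> 0.75), c (rank 1 -> 1.0), d (rank 4 -> 0.25)
  expect_equal(res$curve$gene_id, c("a", "c", "d"))
  expect_equal(res$curve$score, c(0.75, 1, 0.25))
  expect_equal(res$curve$running_mean, c(0.75, 0.875, 2 / 3))
  expect_equal(res$argmax_gene, "c")
})

test_that("monotone method-2 ranks give a non-increasing curve after its start", {
  set.seed(71)
  for (rep in 1:10) {
    m <- sample(5:20, 1)
    g <- data.table::data.table(gene_id = sprintf("g%02d", 1:m),
                                min_pvalue = sort(runif(m)))
    ranks <- stats::setNames(seq_len(m), g$gene_id)  # same order both methods
    rm_ <- cumulative_average_rank(g, ranks)$curve$running_mean
    expect_true(all(diff(rm_) <= 1e-12))
  }
})

test_that("QQ tables use uniform quantiles and beta order-statistic bands", {
  rs <- data.table::data.table(chrom = "chr1", start = 1L, pvalue = 0.5)
  qm <- qq_manhattan_tables(rs)
  expect_equal(qm$qq$expected, -log10(0.5))
  expect_equal(qm$bonferroni, 0.05)

  n <- 200
  rs_u <- data.table::data.table(chrom = "chr1", start = seq_len(n),
                                 pvalue = (seq_len(n) - 0.5) / n)
  qm_u <- qq_manhattan_tables(rs_u)
  # a perfectly uniform grid tracks the diagonal inside the band
  expect_equal(qm_u$qq$observed, qm_u$qq$expected, tolerance = 1e-12)
  expect_true(all(qm_u$qq$observed >= qm_u$qq$band_lo - 1e-12))
  expect_true(all(qm_u$qq$observed <= qm_u$qq$band_hi + 1e-12))
  # band endpoints equal beta order-statistic quantiles (direct oracle)
  i <- seq_len(n)
  expect_equal(qm_u$qq$band_lo, -log10(qbeta(0.975, i, n - i + 1)))
  expect_equal(qm_u$qq$band_hi, -log10(qbeta(0.025, i, n - i + 1)))

  expect_warning(qq_manhattan_tables(
    data.table::data.table(chrom = "chr1", start = 1L, pvalue = 0)), "clipped")
})

test_that("joint simulation puts large effects high in both methods' rankings", {
  # 6 regions, 3 with effects of increasing size; both methods run on the
  # same data; region ranks should correlate with the known effect order
  cfg <- sim_config(seed = 17, chrom_layout = list(
    list(chrom = "chr1", cpgs = rep(70L, 6), spacing = c(2L, 12L), gap = 400L)),
    missing_rate = 0, depth_mean = 25)
  pos <- simulate_positions(cfg)
  meta <- simulate_metadata(cfg)
  amp <- c(0, 0, 0, 0.8, 1.4, 2.0)
  b1 <- unlist(lapply(seq_len(6), function(r) {
    u <- seq(0, 1, length.out = 70)
    smooth_bump(amp[r])(u)
  }))
  eff <- make_true_effects(pos, beta0 = 0.3, beta_disease = b1,
                           beta_age = 0.003)
  counts <- simulate_counts(pos, meta, eff, cfg)
  merged <- filter_sites(merge_strands(counts), meta)
  part <- partition_regions(unique(merged[, c("chrom", "pos"), with = FALSE]),
                            min_cpgs = 30L)
  fits <- fit_all_regions(merged, meta, part, keep_fits = FALSE)
  sl <- smooth_slopes(sitewise_regression(merged, meta), part, 5L)
  base_stat <- find_bumps(sl, cutoff = 0)
  joined <- merge(fits$summary[, c("region_id", "pvalue"), with = FALSE],
                  base_stat[, c("region_id", "stat"), with = FALSE],
                  by = "region_id")
  # the three largest effects give the three smallest model p-values and
  # the three largest baseline statistics
  expect_gt(stats::cor(-log10(joined$pvalue), joined$stat,
                       method = "spearman"), 0)
  expect_lt(max(joined$pvalue[4:6]), min(joined$pvalue[1:3]))
})
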