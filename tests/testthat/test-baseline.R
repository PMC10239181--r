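test_that("sitewise slopes match closed forms and the least-squares oracle", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:13),
                     group = rep(c("case", "control"), c(9, 4)),
                     age = seq(25, 73, length.out = 13))
  mk_merged <- function(props, valid = rep(TRUE, 13)) {
    data.table::data.table(chrom = "chr1", pos = 100L,
                           sample_id = meta$sample_id,
                           meth = as.integer(round(props * 10)), total = 10L,
                           valid = valid)
  }
  # no age adjustment: slope is the difference of group mean proportions
  props <- c(rep(0.8, 9), rep(0.3, 4))
  sl <- sitewise_regression(mk_merged(props), meta, use_age = FALSE)
  expect_equal(sl$slope, 0.5)
  # identical proportions: slope 0
  expect_equal(sitewise_regression(mk_merged(rep(0.4, 13)), meta)$slope, 0)
  # with age: match lm() on random proportions, many CpGs
  set.seed(41)
  for (i in 1:10) {
    props <- round(runif(13), 1)
    sl <- sitewise_regression(mk_merged(props), meta, use_age = TRUE)
    ora <- lm(props ~ disease + age,
              data = data.frame(disease = c(rep(1, 9), rep(0, 4)),
                                age = meta$age))
    expect_equal(sl$slope, unname(coef(ora)["disease"]), tolerance = 1e-10)
  }
  # fewer than 2 informative samples in a group: undefined, flagged
  sl <- sitewise_regression(mk_merged(props, valid = c(rep(TRUE, 9),
                                                       TRUE, rep(FALSE, 3))),
                            meta)
  expect_true(is.na(sl$slope))
  expect_false(sl$ok)
})

test_that("slope smoothing is a within-region running mean", {
  part <- data.table::data.table(chrom = "chr1",
                                 pos = c(10L, 20L, 30L, 40L, 50L, 400L, 410L),
                                 region_id = c(rep("r1", 5), rep("r2", 2)),
                                 n_cpgs = c(rep(5L, 5), 2L, 2L),
                                 eligible = FALSE)
  slopes <- data.table::data.table(chrom = "chr1", pos = part$pos,
                                   slope = c(1, 2, 3, 4, 5, 10, 20),
                                   n_used = 13L, ok = TRUE)
  sm <- smooth_slopes(slopes, part, window_cpgs = 3L)
  # hand-computed truncated centered windows inside r1
  expect_equal(sm[sm$region_id == "r1", ]$smoothed_slope,
               c(1.5, 2, 3, 4, 4.5))
  # no smoothing across the region boundary; short region averages itself
  expect_equal(sm[sm$region_id == "r2", ]$smoothed_slope, c(15, 15))
  # window 1 is the identity; constants are unchanged
  expect_equal(smooth_slopes(slopes, part, 1L)$smoothed_slope, slopes$slope)
  cn <- data.table::copy(slopes)[, slope := 2]
  expect_equal(smooth_slopes(cn, part, 3L)$smoothed_slope, rep(2, 7))
  # whole-region window conserves the region mean
  sm_all <- smooth_slopes(slopes, part, 9L)
  expect_equal(mean(sm_all[sm_all$region_id == "r1", ]$smoothed_slope),
               mean(slopes$slope[1:5]))
  expect_error(smooth_slopes(slopes, part, 0L), ">= 1")
})

test_that("bump candidacy uses the mean absolute smoothed slope", {
  sm <- data.table::data.table(
    chrom = "chr1", pos = c(1L, 2L, 3L, 11L, 12L, 13L, 21L, 22L, 23L),
    region_id = rep(c("a", "b", "c"), each = 3),
    smoothed_slope = c(0.3, 0.3, 0.3, 0.1, 0.1, 0.1, 0.3, -0.3, 0.3))
  b <- find_bumps(sm, cutoff = 0.2)
  expect_setequal(b$region_id, c("a", "c"))
  expect_equal(b[b$region_id == "a", ]$mean_abs_beta, 0.3)
  # absolute value is taken before averaging
  expect_equal(b[b$region_id == "c", ]$mean_abs_beta, 0.3)
  expect_equal(nrow(find_bumps(sm[0], 0.2)), 0L)
})

test_that("permutation q-values are deterministic and match exhaustive enumeration", {
  # 2-vs-2 toy design, one strong region and one null region
  meta <- data.frame(sample_id = sprintf("s%d", 1:4),
                     group = rep(c("case", "control"), each = 2),
                     age = c(40, 50, 45, 55))
  pos_r1 <- seq(100L, by = 10L, length.out = 5L)
  pos_r2 <- seq(1000L, by = 10L, length.out = 5L)
  props <- rbind(matrix(c(0.9, 0.9, 0.1, 0.1), 5, 4, byrow = TRUE),
                 matrix(c(0.5, 0.45, 0.55, 0.5), 5, 4, byrow = TRUE))
  merged <- data.table::data.table(
    chrom = "chr1", pos = rep(c(pos_r1, pos_r2), each = 4),
    sample_id = rep(meta$sample_id, 10),
    meth = as.integer(round(t(props) * 20)), total = 20L, valid = TRUE)
  part <- partition_regions(unique(merged[, c("chrom", "pos")]),
                            gap_bp = 200L, min_cpgs = 3L)
  sl <- sitewise_regression(merged, meta, use_age = FALSE)
  sm <- smooth_slopes(sl, part, 3L)
  cand <- find_bumps(sm, cutoff = 0.05)
  expect_gte(nrow(cand), 1L)

  # all 6 balanced label assignments, enumerated explicitly
  perms <- t(apply(utils::combn(4, 2), 2, function(ix) {
    v <- c(0, 0, 0, 0); v[ix] <- 1; v
  }))
  q1 <- permutation_qvalues(cand, merged, meta, part, window_cpgs = 3L,
                            cutoff = 0.05, use_age = FALSE,
                            permutations = perms)

  # brute-force oracle: recompute every permutation's per-region statistic
  # with plain loops
  stat_brute <- function(D) {
    stats <- c()
    for (rid in unique(part$region_id)) {
      ppos <- part$pos[part$region_id == rid]
      sl_r <- vapply(ppos, function(pp) {
        sub <- merged[merged$pos == pp, ]
        pr <- sub$meth / sub$total
        mean(pr[D == 1]) - mean(pr[D == 0])
      }, numeric(1))
      smv <- vapply(seq_along(sl_r), function(i) {
        mean(sl_r[max(1, i - 1):min(length(sl_r), i + 1)])
      }, numeric(1))
      stats <- c(stats, mean(abs(smv)))
    }
    stats
  }
  null_stats <- unlist(lapply(seq_len(nrow(perms)),
                              function(i) stat_brute(perms[i, ])))
  q_oracle <- vapply(sort(cand$stat, decreasing = TRUE), function(s) {
    min(1, sum(null_stats >= s) / (nrow(perms) * sum(cand$stat >= s)))
  }, numeric(1))
  q_oracle <- rev(cummin(rev(q_oracle)))
  expect_equal(q1$qvalue, q_oracle)

  # seeded runs are reproducible
  qa <- permutation_qvalues(cand, merged, meta, part, n_perm = 10L, seed = 7L,
                            window_cpgs = 3L, cutoff = 0.05, use_age = FALSE)
  qb <- permutation_qvalues(cand, merged, meta, part, n_perm = 10L, seed = 7L,
                            window_cpgs = 3L, cutoff = 0.05, use_age = FALSE)
  expect_identical(qa, qb)
  # q-values never increase with the statistic
  expect_true(all(diff(qa$qvalue) >= 0))  # ordered by decreasing stat
  expect_error(permutation_qvalues(cand, merged, meta, part, n_perm = 0L),
               "n_perm")
})

test_that("a bump above every permutation statistic gets q = 0", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     group = rep(c("case", "control"), each = 3), age = 50)
  pos <- seq(100L, by = 10L, length.out = 6L)
  # extreme separation: cases fully methylated, controls fully not
  merged <- data.table::data.table(
    chrom = "chr1", pos = rep(pos, each = 6), sample_id = rep(meta$sample_id, 6),
    meth = rep(c(30L, 30L, 30L, 0L, 0L, 0L), 6), total = 30L, valid = TRUE)
  part <- partition_regions(unique(merged[, c("chrom", "pos")]), min_cpgs = 3L)
  sl <- sitewise_regression(merged, meta, use_age = FALSE)
  cand <- find_bumps(smooth_slopes(sl, part, 3L), cutoff = 0.2)
  # scrambled assignments only (observed labeling and its complement are
  # excluded), so every null statistic is below the observed one
  perms <- rbind(c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1),
                 c(1, 0, 0, 1, 1, 0), c(0, 1, 1, 0, 0, 1))
  q <- permutation_qvalues(cand, merged, meta, part, window_cpgs = 3L,
                           cutoff = 0.2, use_age = FALSE, permutations = perms)
  expect_equal(q$qvalue, 0)
})
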