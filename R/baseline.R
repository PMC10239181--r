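# Vectorized per-CpG OLS of methylation proportion on disease (+ age).
# P: CpG x sample proportion matrix with NA for missing; D, age per sample.
# Returns the disease coefficient per CpG (NA where undefined).
site_slopes_engine <- function(P, D, age = NULL) {
  Mv <- !is.na(P)
  P0 <- P; P0[!Mv] <- 0
  Mn <- Mv * 1
  n_case <- Mn %*% D
  n_ctrl <- Mn %*% (1 - D)
  ok <- drop(n_case) >= 2 & drop(n_ctrl) >= 2
  if (is.null(age)) {
    mean_case <- (P0 %*% D) / pmax(n_case, 1)
    mean_ctrl <- (P0 %*% (1 - D)) / pmax(n_ctrl, 1)
    slope <- drop(mean_case - mean_ctrl)
  } else {
    S1 <- drop(Mn %*% rep(1, length(D)))
    SD <- drop(Mn %*% D); SA <- drop(Mn %*% age)
    SDD <- SD  # D is 0/1 so D^2 = D
    SAA <- drop(Mn %*% age^2); SDA <- drop(Mn %*% (D * age))
    Sy <- rowSums(P0); SyD <- drop(P0 %*% D); SyA <- drop(P0 %*% age)
    det3 <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33)
      a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
        a13 * (a21 * a32 - a22 * a31)
    dA <- det3(S1, SD, SA, SD, SDD, SDA, SA, SDA, SAA)
    dN <- det3(S1, Sy, SA, SD, SyD, SDA, SA, SyA, SAA)
    scale <- pmax(S1, 1) * pmax(SAA, 1)  # rank-deficiency guard scale
    ok <- ok & abs(dA) > 1e-10 * scale
    slope <- ifelse(ok, dN / dA, NA_real_)
  }
  slope[!ok] <- NA_real_
  list(slope = slope, n_used = drop(n_case + n_ctrl), ok = ok)
}

# Build the CpG x sample proportion matrix from a merged/filtered table.
proportion_matrix <- function(merged, sample_ids) {
  x <- data.table::as.data.table(merged)
  if ("valid" %in% names(x)) x <- x[valid == TRUE]
  sites <- unique(x[, c("chrom", "pos"), with = FALSE])
  data.table::setorderv(sites, c("chrom", "pos"))
  key <- paste(sites$chrom, sites$pos)
  P <- matrix(NA_real_, nrow(sites), length(sample_ids),
              dimnames = list(NULL, sample_ids))
  ri <- match(paste(x$chrom, x$pos), key)
  ci <- match(x$sample_id, sample_ids)
  P[cbind(ri, ci)] <- x$meth / x$total
  list(sites = sites, P = P)
}

#' Per-CpG ordinary least squares slope estimates
#'
#' First stage of the bump-style baseline: at each CpG, ordinary linear
#' regression of the per-sample methylation proportion (`meth/total`) on
#' the disease indicator and age; the slope is the disease coefficient.
#' Samples invalid at a CpG are excluded; the slope is undefined (NA,
#' `ok = FALSE`) when fewer than 2 informative samples remain in either
#' group or the design is rank-deficient at that CpG.
#'
#' @param merged merged/filtered counts with `valid` flags.
#' @param sample_meta metadata with `sample_id`, `group`, optional `age`.
#' @param use_age include age as a covariate (default TRUE when present).
#' @return `data.table` with `chrom`, `pos`, `slope`, `n_used`, `ok`.
#' @export
sitewise_regression <- function(merged, sample_meta,
                                use_age = "age" %in% names(sample_meta)) {
  design <- make_design(sample_meta)
  pm <- proportion_matrix(merged, design$sample_id)
  eng <- site_slopes_engine(pm$P, design$disease,
                            if (use_age) design$age else NULL)
  out <- data.table::copy(pm$sites)
  out[, `:=`(slope = eng$slope, n_used = eng$n_used, ok = eng$ok)]
  out[]
}

#' Smooth site slopes within regions
#'
#' Centered running mean over `window_cpgs` CpGs, computed strictly within
#' each region (no smoothing across region boundaries); windows truncate at
#' region edges and regions shorter than the window average all their CpGs.
#' Undefined slopes are dropped from window averages.
#'
#' @param slopes [sitewise_regression()] output.
#' @param partition [partition_regions()] output giving region membership.
#' @param window_cpgs window width in CpGs (>= 1).
#' @return `slopes` with a `smoothed_slope` column and `region_id`.
#' @export
smooth_slopes <- function(slopes, partition, window_cpgs = 5L) {
  if (window_cpgs < 1L) stop("window must be >= 1")
  x <- data.table::as.data.table(slopes)
  part <- data.table::as.data.table(partition)[, c("chrom", "pos", "region_id"),
                                               with = FALSE]
  x <- part[x, on = c("chrom", "pos")]
  if (anyNA(x$region_id)) stop("slopes outside the partition")
  data.table::setorderv(x, c("chrom", "pos"))
  half <- (as.integer(window_cpgs) - 1L) %/% 2L
  run_mean <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      w <- v[max(1L, i - half):min(n, i + half)]
      out[i] <- mean(w, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  x[, smoothed_slope := run_mean(slope), by = region_id]
  x[]
}

#' Identify candidate bumps by mean absolute smoothed slope
#'
#' A region is a candidate when the mean of |smoothed slope| over its CpGs
#' reaches `cutoff` (default 0.2, on the methylation-proportion scale).
#'
#' @param smoothed [smooth_slopes()] output.
#' @param cutoff minimum regional mean |smoothed slope|.
#' @return `data.table` of candidates: `region_id`, `chrom`, `start`,
#'   `end`, `n_cpgs`, `mean_abs_beta`, `stat` (equal to `mean_abs_beta`).
#' @export
find_bumps <- function(smoothed, cutoff = 0.2) {
  x <- data.table::as.data.table(smoothed)
  if (nrow(x) == 0L)
    return(data.table::data.table(region_id = character(0),
                                  chrom = character(0), start = integer(0),
                                  end = integer(0), n_cpgs = integer(0),
                                  mean_abs_beta = numeric(0),
                                  stat = numeric(0)))
  stats <- x[, .(chrom = chrom[1], start = min(pos), end = max(pos),
                 n_cpgs = .N,
                 mean_abs_beta = mean(abs(smoothed_slope), na.rm = TRUE)),
             by = region_id]
  stats[is.nan(mean_abs_beta), mean_abs_beta := NA_real_]
  out <- stats[!is.na(mean_abs_beta) & mean_abs_beta >= cutoff]
  out[, stat := mean_abs_beta]
  data.table::setorderv(out, c("chrom", "start"))
  out[]
}

#' Permutation-based q-values for candidate bumps
#'
#' Re-assigns disease labels genome-wide (group sizes fixed), re-runs the
#' full sitewise-regression / smoothing / bump-statistic pipeline per
#' permutation, and pools every region's null statistic. For an observed
#' candidate with statistic s, `q = [pooled null count >= s] /
#' (n_perm * [observed candidates >= s])`, clipped to `[0, 1]` and
#' monotonized so q never increases with the statistic.
#'
#' @param candidates [find_bumps()] output.
#' @param merged merged/filtered counts.
#' @param sample_meta metadata.
#' @param partition [partition_regions()] output.
#' @param n_perm number of permutations (default 40).
#' @param seed RNG seed for label permutation.
#' @param window_cpgs,cutoff smoothing window and bump cutoff, matching the
#'   observed analysis.
#' @param use_age include age in the sitewise regressions.
#' @param permutations optional explicit permutation set: a matrix with one
#'   0/1 disease-label row per permutation (overrides `n_perm`/`seed`),
#'   e.g. for exhaustive enumeration in small designs.
#' @return `candidates` with a `qvalue` column, ordered by decreasing
#'   statistic.
#' @export
permutation_qvalues <- function(candidates, merged, sample_meta, partition,
                                n_perm = 40L, seed = 1L, window_cpgs = 5L,
                                cutoff = 0.2,
                                use_age = "age" %in% names(sample_meta),
                                permutations = NULL) {
  if (is.null(permutations) && n_perm < 1L) stop("n_perm must be >= 1")
  cand <- data.table::as.data.table(candidates)
  if (nrow(cand) == 0L) {
    cand[, qvalue := numeric(0)]
    return(cand[])
  }
  design <- make_design(sample_meta)
  D_obs <- design$disease
  age <- if (use_age) design$age else NULL
  pm <- proportion_matrix(merged, design$sample_id)
  part <- data.table::as.data.table(partition)[, c("chrom", "pos", "region_id"),
                                               with = FALSE]
  sites <- part[pm$sites, on = c("chrom", "pos")]
  if (anyNA(sites$region_id)) stop("counts outside the partition")
  region_of <- sites$region_id
  half <- (as.integer(window_cpgs) - 1L) %/% 2L
  reg_index <- split(seq_along(region_of), region_of)

  stat_one <- function(D) {
    sl <- site_slopes_engine(pm$P, D, age)$slope
    vapply(reg_index, function(idx) {
      v <- sl[idx]; n <- length(v)
      sm <- numeric(n)
      for (i in seq_len(n))
        sm[i] <- mean(v[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
      m <- mean(abs(sm), na.rm = TRUE)
      if (is.nan(m)) NA_real_ else m
    }, numeric(1))
  }

  if (is.null(permutations)) {
    permutations <- with_seed(seed, t(vapply(seq_len(n_perm),
                                             function(i) sample(D_obs),
                                             numeric(length(D_obs)))))
  }
  n_perm <- nrow(permutations)
  null_stats <- unlist(lapply(seq_len(n_perm), function(i)
    stat_one(as.numeric(permutations[i, ]))), use.names = FALSE)
  null_stats <- null_stats[!is.na(null_stats)]

  data.table::setorderv(cand, "stat", order = -1L)
  obs <- cand$stat
  q <- vapply(obs, function(s) {
    sum(null_stats >= s) / (n_perm * sum(obs >= s))
  }, numeric(1))
  q <- pmin(pmax(q, 0), 1)
  # enforce q non-increasing in the statistic (descending order here)
  q <- rev(cummin(rev(q)))
  cand[, qvalue := q]
  cand[]
}

#' Run the full two-stage baseline
#'
#' Convenience wrapper: sitewise regression, within-region smoothing, bump
#' filtering, and permutation q-values.
#'
#' @inheritParams permutation_qvalues
#' @return list with `slopes` (smoothed sitewise table) and `bumps`
#'   (candidates with q-values).
#' @export
run_baseline <- function(merged, sample_meta, partition, window_cpgs = 5L,
                         cutoff = 0.2, n_perm = 40L, seed = 1L,
                         use_age = "age" %in% names(sample_meta)) {
  slopes <- sitewise_regression(merged, sample_meta, use_age)
  sm <- smooth_slopes(slopes, partition, window_cpgs)
  bumps <- find_bumps(sm, cutoff)
  bumps <- permutation_qvalues(bumps, merged, sample_meta, partition,
                               n_perm = n_perm, seed = seed,
                               window_cpgs = window_cpgs, cutoff = cutoff,
                               use_age = use_age)
  list(slopes = sm, bumps = bumps)
}
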