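#' CpG-level overlap between two region sets
#'
#' Two regions (one from each method) overlap when they share at least one
#' CpG position; each such pair is emitted with its exact shared-CpG count.
#' Swapping the inputs transposes the table.
#'
#' @param regions_a,regions_b tables with `chrom`, `pos`, `region_id`
#'   (CpG membership lists, e.g. [partition_regions()] output).
#' @return `data.table` with `region_id_a`, `region_id_b`,
#'   `n_shared_cpgs`.
#' @export
overlap_regions <- function(regions_a, regions_b) {
  a <- data.table::as.data.table(regions_a)[, c("chrom", "pos", "region_id"),
                                            with = FALSE]
  b <- data.table::as.data.table(regions_b)[, c("chrom", "pos", "region_id"),
                                            with = FALSE]
  for (x in list(a, b)) {
    dup <- x[, .N, by = c("region_id", "chrom", "pos")][N > 1L]
    if (nrow(dup))
      stop("duplicate CpG ", dup$chrom[1], ":", dup$pos[1],
           " within region ", dup$region_id[1])
  }
  data.table::setnames(a, "region_id", "region_id_a")
  data.table::setnames(b, "region_id", "region_id_b")
  j <- merge(a, b, by = c("chrom", "pos"), allow.cartesian = TRUE)
  out <- j[, .(n_shared_cpgs = .N), by = c("region_id_a", "region_id_b")]
  data.table::setorderv(out, c("region_id_a", "region_id_b"))
  out[]
}

#' Rank results by significance with genomic tie-breaking
#'
#' Rank 1 is the smallest p- or q-value; exact ties are ordered by
#' `(chrom, start)` so ranking is deterministic. Rows with missing values
#' are excluded with a warning.
#'
#' @param results table containing the significance column plus `chrom` and
#'   `start`.
#' @param key name of the significance column (e.g. `"pvalue"`).
#' @return `results` (minus missing-value rows) with a `rank` column.
#' @export
rank_by_significance <- function(results, key = "pvalue") {
  x <- data.table::as.data.table(results)
  stopifnot(key %in% names(x), all(c("chrom", "start") %in% names(x)))
  miss <- is.na(x[[key]])
  if (any(miss)) {
    warning(sum(miss), " result(s) with missing ", key, " excluded")
    x <- x[!miss]
  }
  ord <- order(x[[key]], x$chrom, x$start)
  x[ord, rank := seq_len(.N)]
  x[]
}

#' Cumulative average rank-concordance curve between two methods
#'
#' Walks method 1's genes in ascending order of their minimum region
#' p-value. Each gene present among method 2's M ranked genes contributes
#' the normalized reversed rank `(M - rank + 1) / M` (1 = method 2's most
#' significant gene); the curve is the running mean of these scores over
#' matched genes so far. Unmatched genes emit no point. The gene where the
#' running mean attains its maximum marks the strongest agreement.
#'
#' @param genes_method1 table with `gene_id` and `min_pvalue` (minimum
#'   region p-value over the gene's regions).
#' @param ranks_method2 named integer vector: method 2 rank (1 = most
#'   significant) per gene, over its M genes.
#' @return list with `curve` (`data.table`: `gene_id`, `min_pvalue`,
#'   `score`, `running_mean`) and `argmax_gene` (first gene attaining the
#'   maximum running mean; `NA` if no gene matches).
#' @export
cumulative_average_rank <- function(genes_method1, ranks_method2) {
  g <- data.table::as.data.table(genes_method1)
  stopifnot(all(c("gene_id", "min_pvalue") %in% names(g)))
  if (nrow(g) == 0L) stop("empty method-1 gene list")
  M <- length(ranks_method2)
  data.table::setorderv(g, c("min_pvalue", "gene_id"))
  matched <- g[gene_id %in% names(ranks_method2)]
  if (nrow(matched) == 0L)
    return(list(curve = data.table::data.table(gene_id = character(0),
                                               min_pvalue = numeric(0),
                                               score = numeric(0),
                                               running_mean = numeric(0)),
                argmax_gene = NA_character_))
  score <- (M - as.numeric(ranks_method2[matched$gene_id]) + 1) / M
  rmean <- cumsum(score) / seq_along(score)
  curve <- data.table::data.table(gene_id = matched$gene_id,
                                  min_pvalue = matched$min_pvalue,
                                  score = score, running_mean = rmean)
  list(curve = curve, argmax_gene = matched$gene_id[which.max(rmean)])
}

#' Plot-ready QQ and Manhattan tables for region p-values
#'
#' The QQ table pairs sorted observed p-values with uniform expected
#' quantiles `(i - 0.5) / n` and a 95% null band from the beta
#' order-statistic quantiles of uniform samples, all on the -log10 scale.
#' The Manhattan table carries region start positions and -log10 p-values;
#' the nominal and Bonferroni thresholds travel as attributes and columns
#' of the returned list.
#'
#' @param region_summary table with `chrom`, `start`, `pvalue`.
#' @param alpha nominal threshold (default 0.05).
#' @param n_tests number of tests for the Bonferroni line (default: number
#'   of finite p-values).
#' @return list with `qq` (`data.table`: `expected`, `observed`,
#'   `band_lo`, `band_hi`, -log10 scale), `manhattan` (`data.table`:
#'   `chrom`, `start`, `neglog10_p`), `alpha`, and
#'   `bonferroni` (the per-region threshold).
#' @export
qq_manhattan_tables <- function(region_summary, alpha = 0.05,
                                n_tests = NULL) {
  x <- data.table::as.data.table(region_summary)
  stopifnot(all(c("chrom", "start", "pvalue") %in% names(x)))
  p <- x$pvalue
  keep <- !is.na(p)
  p <- p[keep]
  if (any(p == 0)) {
    warning("p-values of 0 clipped to smallest representable")
    p[p == 0] <- .Machine$double.xmin
  }
  if (any(p < 0 | p > 1)) stop("p-values outside (0, 1]")
  n <- length(p)
  if (is.null(n_tests)) n_tests <- n
  i <- seq_len(n)
  sorted <- sort(p)
  qq <- data.table::data.table(
    expected = -log10((i - 0.5) / n),
    observed = -log10(sorted),
    band_lo = -log10(stats::qbeta(0.975, i, n - i + 1)),
    band_hi = -log10(stats::qbeta(0.025, i, n - i + 1)))
  man <- data.table::data.table(chrom = x$chrom[keep], start = x$start[keep],
                                neglog10_p = -log10(pmax(x$pvalue[keep],
                                                         .Machine$double.xmin)))
  list(qq = qq, manhattan = man, alpha = alpha,
       bonferroni = bonferroni_threshold(alpha, n_tests))
}

#' Gene-level minimum p-values from region results and gene links
#'
#' @param region_summary table with `region_id` and `pvalue`.
#' @param links DMR-gene link table (`region_id`, `gene_id`), e.g. the
#'   `links` element of [assign_dmrs()].
#' @return `data.table` with `gene_id` and `min_pvalue`.
#' @export
gene_min_pvalues <- function(region_summary, links) {
  rs <- data.table::as.data.table(region_summary)[, c("region_id", "pvalue"),
                                                  with = FALSE]
  l <- data.table::as.data.table(links)[, c("region_id", "gene_id"),
                                        with = FALSE]
  j <- merge(unique(l), rs, by = "region_id")
  out <- j[, .(min_pvalue = min(pvalue, na.rm = TRUE)), by = gene_id]
  data.table::setorderv(out, "min_pvalue")
  out[]
}
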