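#' Build design values from sample metadata
#'
#' @param sample_meta table with `sample_id`, `group` (`case`/`control`)
#'   and `age`.
#' @return data.frame with `sample_id`, `disease` (1 = case) and `age`.
#' @export
make_design <- function(sample_meta) {
  stopifnot(all(c("sample_id", "group") %in% names(sample_meta)))
  bad <- setdiff(unique(sample_meta$group), c("case", "control"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  data.frame(sample_id = sample_meta$sample_id,
             disease = as.integer(sample_meta$group == "case"),
             age = if ("age" %in% names(sample_meta)) sample_meta$age else NULL)
}

#' Cast a merged count table into CpG-by-sample matrices for one region
#'
#' @param merged merged/filtered counts (`chrom pos sample_id meth total
#'   valid`).
#' @param region_positions the region's CpG positions (same chromosome).
#' @param sample_ids column order for the matrices.
#' @return list with matrices `meth` and `total` (invalid or missing
#'   records have `total = 0`).
#' @export
region_matrices <- function(merged, region_positions, sample_ids) {
  x <- data.table::as.data.table(merged)[pos %in% region_positions]
  if ("valid" %in% names(x)) x <- x[valid == TRUE]
  n_cpg <- length(region_positions); n_s <- length(sample_ids)
  meth <- matrix(0L, n_cpg, n_s, dimnames = list(NULL, sample_ids))
  total <- matrix(0L, n_cpg, n_s, dimnames = list(NULL, sample_ids))
  ri <- match(x$pos, region_positions); ci <- match(x$sample_id, sample_ids)
  ok <- !is.na(ri) & !is.na(ci)
  meth[cbind(ri[ok], ci[ok])] <- x$meth[ok]
  total[cbind(ri[ok], ci[ok])] <- x$total[ok]
  list(meth = meth, total = total)
}

#' Fit the regional model over every eligible region
#'
#' Loops over eligible regions of a partition, fits each independently and
#' collects region summaries. Per-region fit failures are logged with a
#' warning and excluded, never fatal.
#'
#' @param merged filtered merged counts ([filter_sites()] output).
#' @param sample_meta sample metadata.
#' @param partition [partition_regions()] output.
#' @param spec a [spline_spec()]; regions with fewer CpGs than `spec$df`
#'   get a basis shrunk to fit.
#' @param config a [model_config()].
#' @param keep_fits keep the full `region_fit` objects (default TRUE).
#' @return list with `summary` (`data.table`: `region_id`, `chrom`,
#'   `start`, `end`, `n_cpgs`, `edf1`, `phi`, `lambda1`, `pvalue`,
#'   `converged`) and `fits` (named list of `region_fit`, or NULL).
#' @export
fit_all_regions <- function(merged, sample_meta, partition,
                            spec = spline_spec(), config = model_config(),
                            keep_fits = TRUE) {
  part <- data.table::as.data.table(partition)
  design <- make_design(sample_meta)
  rids <- unique(part[eligible == TRUE]$region_id)
  rows <- vector("list", length(rids))
  fits <- if (keep_fits) vector("list", length(rids)) else NULL
  merged <- data.table::as.data.table(merged)
  for (k in seq_along(rids)) {
    rid <- rids[k]
    pr <- part[region_id == rid]
    res <- tryCatch({
      sp <- if (spec$df > 1L && spec$df >= nrow(pr))
        spline_spec(max(3L, nrow(pr) - 1L), spec$degree, spec$penalty_order)
      else spec
      bas <- build_basis(pr$pos, sp)
      mats <- region_matrices(merged[chrom == pr$chrom[1]], pr$pos,
                              design$sample_id)
      fit_region(mats$meth, mats$total, design, bas, config, region_id = rid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("region ", rid, " failed: ", conditionMessage(res))
      next
    }
    rows[[k]] <- data.table::data.table(
      region_id = rid, chrom = pr$chrom[1], start = min(pr$pos),
      end = max(pr$pos), n_cpgs = nrow(pr), edf1 = res$edf[["beta1"]],
      phi = res$phi, lambda1 = rep_len(res$lambda, 2)[2],
      pvalue = res$region_pvalue,
      converged = res$converged)
    if (keep_fits) fits[[k]] <- res
  }
  summary <- data.table::rbindlist(rows)
  if (keep_fits) {
    names(fits) <- rids
    fits <- fits[!vapply(fits, is.null, logical(1))]
  }
  list(summary = summary, fits = fits)
}

#' Per-CpG curve output table across fitted regions
#'
#' @param fits named list of `region_fit` objects.
#' @param partition the partition used (for chromosome labels).
#' @param ci_level confidence level for the disease-curve band.
#' @return `data.table` `region_id chrom pos beta0 beta1 se1 beta2 ci1_lo
#'   ci1_hi` (logit scale).
#' @export
region_curves_table <- function(fits, partition, ci_level = 0.95) {
  part <- data.table::as.data.table(partition)
  chrom_of <- part[, .(chrom = chrom[1]), by = region_id]
  out <- lapply(fits, function(f) {
    ci <- pointwise_intervals(f, ci_level)
    data.table::data.table(region_id = f$region_id, pos = f$positions,
                           beta0 = f$curves$beta0, beta1 = f$curves$beta1,
                           se1 = f$curves$se_beta1,
                           beta2 = if (f$has_age) f$curves$beta2 else NA_real_,
                           ci1_lo = ci$lo, ci1_hi = ci$hi)
  })
  res <- data.table::rbindlist(out)
  res <- chrom_of[res, on = "region_id"]
  data.table::setcolorder(res, c("region_id", "chrom", "pos"))
  res[]
}
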