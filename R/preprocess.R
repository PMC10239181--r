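#' Merge forward and reverse strand counts with a concordance check
#'
#' A sample x CpG observation is valid only when both strands have depth of
#' at least `min_strand_depth` and the two strand-wise methylation
#' proportions differ by less than `max_prop_diff` (strict); valid records
#' get `meth = meth_F + meth_R`, `total = total_F + total_R`. A CpG seen on
#' one strand only cannot be concordance-checked and is invalid. Invalid
#' records are kept with zeroed counts and `valid = FALSE` so downstream
#' coverage accounting can see them.
#'
#' @param strand_counts StrandCounts table (see [read_counts()]).
#' @param min_strand_depth minimum reads required on each strand (default 3).
#' @param max_prop_diff maximum allowed |proportion difference| between
#'   strands (default 0.2, exclusive).
#' @return `data.table` with `chrom`, `pos`, `sample_id`, `meth`, `total`,
#'   `valid`, ordered by genome position then sample.
#' @export
merge_strands <- function(strand_counts, min_strand_depth = 3L,
                          max_prop_diff = 0.2) {
  x <- data.table::as.data.table(strand_counts)
  stopifnot(all(c("chrom", "pos", "strand", "sample_id", "meth", "total")
                %in% names(x)))
  dup <- x[, .N, by = c("chrom", "pos", "sample_id", "strand")][N > 1L]
  if (nrow(dup))
    stop("duplicate strand record for (", dup$sample_id[1], ", ",
         dup$chrom[1], ":", dup$pos[1], ", ", dup$strand[1], ")")
  w <- data.table::dcast(x, chrom + pos + sample_id ~ strand,
                         value.var = c("meth", "total"))
  for (cc in c("meth_+", "meth_-", "total_+", "total_-"))
    if (!cc %in% names(w)) w[, (cc) := NA_integer_]
  tf <- w[["total_+"]]; tr <- w[["total_-"]]
  mf <- w[["meth_+"]];  mr <- w[["meth_-"]]
  both <- !is.na(tf) & !is.na(tr) & tf >= min_strand_depth & tr >= min_strand_depth
  # cross-multiplied strict comparison so an exact tie at the threshold
  # (e.g. 3/5 vs 2/5 with 0.2) is invalid despite floating-point rounding
  pd_num <- abs(as.numeric(mf) * tr - as.numeric(mr) * tf)
  thr <- max_prop_diff * as.numeric(tf) * tr
  valid <- both & !is.na(pd_num) & pd_num < thr * (1 - 1e-12)
  out <- w[, c("chrom", "pos", "sample_id"), with = FALSE]
  out[, meth := data.table::fifelse(valid, mf + mr, 0L)]
  out[, total := data.table::fifelse(valid, tf + tr, 0L)]
  out[, valid := valid]
  data.table::setorderv(out, c("chrom", "pos", "sample_id"))
  out[]
}

#' Coverage filter: retain CpGs covered in enough cases and controls
#'
#' A CpG is retained when the number of samples with `valid = TRUE` reaches
#' `min_valid_cases` among cases and `min_valid_controls` among controls
#' (default 6 of 9 and 3 of 4).
#'
#' @param merged output of [merge_strands()].
#' @param sample_meta metadata table with `sample_id` and `group`.
#' @param min_valid_cases,min_valid_controls absolute thresholds.
#' @return the merged table restricted to retained CpGs, genomic order
#'   preserved.
#' @export
filter_sites <- function(merged, sample_meta, min_valid_cases = 6L,
                         min_valid_controls = 3L) {
  x <- data.table::as.data.table(merged)
  meta <- data.table::as.data.table(sample_meta)
  unknown <- setdiff(unique(x$sample_id), meta$sample_id)
  if (length(unknown))
    stop("sample(s) in counts absent from metadata: ",
         paste(unknown, collapse = ", "))
  grp <- meta$group[match(x$sample_id, meta$sample_id)]
  x[, `:=`(vc = valid & grp == "case", vk = valid & grp == "control")]
  keep <- x[, .(ok = sum(vc) >= min_valid_cases & sum(vk) >= min_valid_controls),
            by = c("chrom", "pos")]
  out <- x[keep[ok == TRUE], on = c("chrom", "pos"), nomatch = NULL]
  out[, c("vc", "vk", "ok") := NULL]
  data.table::setorderv(out, c("chrom", "pos", "sample_id"))
  out[]
}

#' Partition retained CpG sites into disjoint regions
#'
#' Splits between consecutive CpGs on the same chromosome whenever their
#' distance is `gap_bp` or more (default 200 bp). Regions with fewer than
#' `min_cpgs` CpGs (default 60) are kept but flagged `eligible = FALSE`;
#' the two-stage baseline analyses all regions while the regional model
#' only fits eligible ones.
#'
#' @param positions `data.table`/data.frame with `chrom` and sorted,
#'   unique `pos` per chromosome (e.g. unique sites of a filtered merged
#'   table).
#' @param gap_bp split threshold in bp (split at distance >= `gap_bp`).
#' @param min_cpgs minimum CpG count for model eligibility.
#' @return `data.table` with one row per CpG: `chrom`, `pos`, `region_id`,
#'   plus attributes none; and per-region summary accessible via
#'   [region_table()].
#' @export
partition_regions <- function(positions, gap_bp = 200L, min_cpgs = 60L) {
  x <- data.table::as.data.table(positions)[, c("chrom", "pos"), with = FALSE]
  x <- unique(x)
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) stop("positions unsorted on ", ch)
  }
  x[, new_region := c(TRUE, diff(pos) >= gap_bp), by = chrom]
  x[, region_idx := cumsum(new_region), by = chrom]
  x[, region_id := sprintf("%s_%05d", chrom, region_idx)]
  x[, n_cpgs := .N, by = region_id]
  x[, eligible := n_cpgs >= min_cpgs]
  x[, c("new_region", "region_idx") := NULL]
  x[]
}

#' Per-region summary of a partition
#'
#' @param partition output of [partition_regions()].
#' @return one row per region: `region_id`, `chrom`, `start`, `end`
#'   (1-based inclusive CpG span), `n_cpgs`, `eligible`.
#' @export
region_table <- function(partition) {
  data.table::as.data.table(partition)[
    , .(chrom = chrom[1], start = min(pos), end = max(pos),
        n_cpgs = .N, eligible = eligible[1]),
    by = region_id]
}

#' Write regions as BED (0-based half-open; name = region id, score = CpG count)
#' @param partition output of [partition_regions()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(partition, path) {
  rt <- region_table(partition)
  bed <- data.table::data.table(chrom = rt$chrom, start = rt$start - 1L,
                                end = rt$end, name = rt$region_id,
                                score = rt$n_cpgs)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write merged counts TSV (`chrom pos sample_id meth total valid`)
#' @param merged output of [merge_strands()] or [filter_sites()].
#' @param path output file.
#' @return the path (write) or the table (read).
#' @export
write_merged <- function(merged, path) {
  data.table::fwrite(merged, path, sep = "\t")
  invisible(path)
}

#' @rdname write_merged
#' @export
read_merged <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("chrom", "pos", "sample_id", "meth", "total", "valid")
                %in% names(x)))
  x
}
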