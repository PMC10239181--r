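FEATURE_CLASSES <- c("upstream_1to5kb", "promoter", "gene_body", "utr5",
                     "exon", "first_exon", "intron", "utr3", "intergenic")

#' Load a gene-feature annotation file
#'
#' BED6+2 layout, tab-separated, no header: `chrom start end gene_id score
#' strand feature_class gene_type`, with BED (0-based, half-open)
#' coordinates. `feature_class` must come from the 9-class structural
#' vocabulary (1-5 kb upstream, promoter, gene body, 5' UTR, exon, first
#' exon, intron, 3' UTR, intergenic) and `gene_type` from
#' `coding`/`lncRNA_antisense`/`lncRNA_other`.
#'
#' @param path feature file path.
#' @return validated `data.table` of features.
#' @export
load_features <- function(path) {
  cols <- c("chrom", "start", "end", "gene_id", "score", "strand",
            "feature_class", "gene_type")
  x <- if (file.size(path) > 0)
    data.table::fread(path, sep = "\t", header = FALSE)
  else data.table::data.table()
  if (nrow(x) == 0L)
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), gene_id = character(0),
                                  score = numeric(0), strand = character(0),
                                  feature_class = character(0),
                                  gene_type = character(0)))
  if (ncol(x) != 8L) stop("feature file must have 8 columns (BED6+2)")
  data.table::setnames(x, cols)
  bad <- which(!x$feature_class %in% FEATURE_CLASSES)
  if (length(bad))
    stop("unknown feature_class '", x$feature_class[bad[1]], "' at line ",
         bad[1], " of ", path)
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop("feature with end <= start at line ", bad[1], " of ", path)
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand at line ", bad[1], " of ", path)
  bad <- which(!x$gene_type %in% c("coding", "lncRNA_antisense", "lncRNA_other"))
  if (length(bad))
    stop("unknown gene_type at line ", bad[1], " of ", path)
  x
}

#' Write a gene-feature table (inverse of [load_features()])
#' @param features feature table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Assign DMRs to genes through structural features
#'
#' A DMR links to gene G when its interval overlaps at least 1 bp of any
#' non-intergenic feature of G; overlap is strand-blind (counts were
#' strand-merged upstream), so a DMR crossing a sense gene and its
#' antisense lncRNA yields two distinct gene records. DMRs overlapping no
#' gene feature (or only intergenic space) are returned separately as
#' unannotated. DMR intervals are 1-based inclusive CpG spans (`start` =
#' first CpG, `end` = last CpG); features use BED convention — the
#' conversion is internal.
#'
#' @param dmrs `data.table` with `region_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `direction`.
#' @param features [load_features()] output.
#' @return list with `links` (one row per DMR-gene-feature link), `dmgs`
#'   (one row per gene: `gene_id`, `n_dmrs`, `dmr_ids`, `feature_classes`,
#'   `directions`) and `unannotated` (DMR ids linking no gene).
#' @export
assign_dmrs <- function(dmrs, features) {
  d <- data.table::as.data.table(dmrs)
  f <- data.table::as.data.table(features)
  if (nrow(d) && any(d$end < d$start))
    stop("DMR with end < start: coordinate convention mismatch?")
  if (nrow(d) == 0L || nrow(f) == 0L) {
    return(list(links = data.table::data.table(region_id = character(0),
                                               gene_id = character(0),
                                               feature_class = character(0)),
                dmgs = data.table::data.table(gene_id = character(0),
                                              n_dmrs = integer(0),
                                              dmr_ids = character(0),
                                              feature_classes = character(0),
                                              directions = character(0)),
                unannotated = if (nrow(d)) d$region_id else character(0)))
  }
  fg <- f[feature_class != "intergenic"]
  links <- if (nrow(fg)) {
    # features: BED half-open [start, end) in 0-based = 1-based [start+1, end]
    q <- GenomicRanges::GRanges(d$chrom,
                                IRanges::IRanges(d$start, d$end))
    s <- GenomicRanges::GRanges(fg$chrom,
                                IRanges::IRanges(fg$start + 1L, fg$end))
    hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    data.table::data.table(
      region_id = d$region_id[S4Vectors::queryHits(hits)],
      gene_id = fg$gene_id[S4Vectors::subjectHits(hits)],
      feature_class = fg$feature_class[S4Vectors::subjectHits(hits)],
      direction = if ("direction" %in% names(d))
        d$direction[S4Vectors::queryHits(hits)] else NA_character_)
  } else {
    data.table::data.table(region_id = character(0), gene_id = character(0),
                           feature_class = character(0),
                           direction = character(0))
  }
  links <- unique(links)
  dmgs <- links[, .(
    n_dmrs = data.table::uniqueN(region_id),
    dmr_ids = paste(sort(unique(region_id)), collapse = ","),
    feature_classes = paste(sort(unique(feature_class)), collapse = ","),
    directions = paste(unique(direction[!is.na(direction)]), collapse = ",")),
    by = gene_id]
  data.table::setorderv(dmgs, "gene_id")
  unannot <- setdiff(d$region_id, links$region_id)
  list(links = links, dmgs = dmgs, unannotated = unannot)
}

#' Direction of differential methylation over a DMR
#'
#' Classifies the disease-effect curve using the CpGs whose pointwise
#' interval excludes zero: `hyper` if the curve is positive at all of them,
#' `hypo` if negative at all, `mixed` if both signs occur, and `none` if no
#' CpG excludes zero.
#'
#' @param fit a [fit_region()] result.
#' @param ci_level confidence level for the pointwise intervals.
#' @param subset_pos optional CpG subset (default: whole region).
#' @return one of `"hyper"`, `"hypo"`, `"mixed"`, `"none"`.
#' @export
direction_summary <- function(fit, ci_level = 0.95, subset_pos = NULL) {
  ci <- pointwise_intervals(fit, ci_level)
  if (!is.null(subset_pos)) ci <- ci[ci$pos %in% subset_pos]
  sig <- ci[ci$lo > 0 | ci$hi < 0]
  if (nrow(sig) == 0L) return("none")
  if (all(sig$est > 0)) return("hyper")
  if (all(sig$est < 0)) return("hypo")
  "mixed"
}

#' Write a DMG table (`gene_id n_dmrs dmr_ids feature_classes directions`)
#' @param dmgs `dmgs` element of [assign_dmrs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dmgs <- function(dmgs, path) {
  data.table::fwrite(dmgs, path, sep = "\t")
  invisible(path)
}

#' Generate a toy feature annotation consistent with simulated coordinates
#'
#' Builds one synthetic gene per intended region plus, for a chosen subset,
#' an antisense lncRNA partner, and one intergenic block per chromosome.
#' Features use BED coordinates. Intended for tests and synthetic
#' pipelines, not for real genomes.
#'
#' @param positions [simulate_positions()] output.
#' @param antisense_regions intended-region labels that also get an
#'   antisense lncRNA overlapping the gene.
#' @return feature `data.table` in [load_features()] layout.
#' @export
toy_features <- function(positions, antisense_regions = character(0)) {
  pos <- data.table::as.data.table(positions)
  regs <- pos[, .(chrom = chrom[1], start = min(pos), end = max(pos)),
              by = region]
  rows <- list()
  for (k in seq_len(nrow(regs))) {
    r <- regs[k]
    gene <- sprintf("GENE_%s", toupper(r$region))
    width <- r$end - r$start + 1L
    mid <- r$start + width %/% 2L
    # BED 0-based half-open
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = r$chrom,
      start = c(r$start - 1L, r$start - 1L, mid - 1L),
      end = c(r$end, mid, r$end),
      gene_id = gene, score = 0L, strand = "+",
      feature_class = c("gene_body", "first_exon", "intron"),
      gene_type = "coding")
    if (r$region %in% antisense_regions) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = r$chrom, start = r$start - 1L, end = r$end,
        gene_id = paste0(gene, "-AS1"), score = 0L, strand = "-",
        feature_class = "exon", gene_type = "lncRNA_antisense")
    }
  }
  for (ch in unique(regs$chrom)) {
    e <- max(regs[chrom == ch]$end)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = ch, start = e + 1000L, end = e + 2000L,
      gene_id = paste0("IGR_", ch), score = 0L, strand = "+",
      feature_class = "intergenic", gene_type = "coding")
  }
  data.table::rbindlist(rows)
}
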