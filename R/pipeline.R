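#' Pipeline configuration
#'
#' Collects every path and tuning parameter of the end-to-end analysis.
#' Defaults reproduce the study conditions: strand depth >= 3 per strand,
#' strand concordance < 0.2, coverage in >= 6 cases and >= 3 controls,
#' region splits at gaps >= 200 bp, model eligibility at >= 60 CpGs,
#' family-wise error control at 0.05 by Bonferroni, a bump cutoff of 0.2
#' with 40 permutations, and a relaxed p < 0.05 threshold for cross-method
#' overlap characterization.
#'
#' @param counts,metadata,features input file paths (StrandCounts TSV,
#'   sample metadata TSV, BED6+2 feature file).
#' @param out_dir output directory (created if absent).
#' @param min_strand_depth,max_prop_diff,min_valid_cases,min_valid_controls
#'   preprocessing thresholds (see [merge_strands()], [filter_sites()]).
#' @param gap_bp,min_cpgs partition parameters (see [partition_regions()]).
#' @param spec,model model parameters ([spline_spec()], [model_config()]).
#' @param alpha family-wise error rate for the Bonferroni rule.
#' @param window_cpgs,cutoff,n_perm,seed baseline parameters.
#' @param relaxed_p relaxed regional threshold used for overlap/rank
#'   comparison.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, features, out_dir,
                            min_strand_depth = 3L, max_prop_diff = 0.2,
                            min_valid_cases = 6L, min_valid_controls = 3L,
                            gap_bp = 200L, min_cpgs = 60L,
                            spec = spline_spec(), model = model_config(),
                            alpha = 0.05, window_cpgs = 5L, cutoff = 0.2,
                            n_perm = 40L, seed = 1L, relaxed_p = 0.05) {
  stopifnot(max_prop_diff > 0, max_prop_diff <= 1, gap_bp >= 1, min_cpgs >= 1,
            alpha > 0, alpha < 1, relaxed_p > 0, relaxed_p <= 1,
            cutoff >= 0, n_perm >= 1)
  structure(list(counts = counts, metadata = metadata, features = features,
                 out_dir = out_dir, min_strand_depth = min_strand_depth,
                 max_prop_diff = max_prop_diff,
                 min_valid_cases = min_valid_cases,
                 min_valid_controls = min_valid_controls, gap_bp = gap_bp,
                 min_cpgs = min_cpgs, spec = spec, model = model,
                 alpha = alpha, window_cpgs = window_cpgs, cutoff = cutoff,
                 n_perm = n_perm, seed = seed, relaxed_p = relaxed_p),
            class = "pipeline_config")
}

#' Run the end-to-end regional differential-methylation analysis
#'
#' Stages, in order: strand merge and concordance filter, sample-coverage
#' filter, region partition, penalized smooth-curve fits with the
#' Bonferroni DMR rule, the two-stage bump baseline with permutation
#' q-values, structural gene annotation of both methods' DMRs, and the
#' cross-method overlap / rank-concordance comparison. All result tables
#' are written under `config$out_dir` together with a run manifest
#' (parameters, seed, input checksums, and the summary accounting: region,
#' DMR and DMG counts and mean CpGs per region/DMR for both methods).
#' Reruns with an identical config and inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param keep_fits keep full per-region fit objects in the returned bundle.
#' @return invisible list with the main intermediate tables: `merged`,
#'   `partition`, `region_summary`, `fits`, `dmrs`, `dmg_smooth`, `bumps`,
#'   `dmg_baseline`, `overlap`, `rank_curve`, `qq_manhattan`, `manifest`.
#' @export
run_pipeline <- function(config, keep_fits = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) message("[dmrsmooth] ", sprintf(...))

  say("reading inputs")
  counts <- read_counts(config$counts)
  meta <- read_sample_meta(config$metadata)
  features <- load_features(config$features)

  say("preprocess: merging strands (%d strand records)", nrow(counts))
  merged <- merge_strands(counts, config$min_strand_depth,
                          config$max_prop_diff)
  filtered <- filter_sites(merged, meta, config$min_valid_cases,
                           config$min_valid_controls)
  sites <- unique(filtered[, c("chrom", "pos"), with = FALSE])
  say("preprocess: %d CpGs retained of %d merged",
      nrow(sites), nrow(unique(merged[, c("chrom", "pos"), with = FALSE])))
  partition <- partition_regions(sites, config$gap_bp, config$min_cpgs)
  rt <- region_table(partition)
  say("partition: %d regions, %d eligible (>= %d CpGs)",
      nrow(rt), sum(rt$eligible), config$min_cpgs)

  say("fitting regional model over eligible regions")
  fit_res <- fit_all_regions(filtered, meta, partition, config$spec,
                             config$model, keep_fits = TRUE)
  rs <- fit_res$summary
  thr <- bonferroni_threshold(config$alpha, max(nrow(rs), 1L))
  rs[, significant := !is.na(pvalue) & pvalue < thr]
  dmr_ids <- rs[significant == TRUE]$region_id
  say("regional model: %d DMRs at Bonferroni threshold %.3g",
      length(dmr_ids), thr)

  say("running two-stage baseline (%d permutations)", config$n_perm)
  baseline <- run_baseline(filtered, meta, partition, config$window_cpgs,
                           config$cutoff, config$n_perm, config$seed)
  base_dmrs <- baseline$bumps[qvalue <= 0.05]
  say("baseline: %d candidate bumps, %d at q <= 0.05",
      nrow(baseline$bumps), nrow(base_dmrs))

  say("annotating DMRs")
  dir_of <- function(rid) {
    f <- fit_res$fits[[rid]]
    if (is.null(f)) NA_character_ else direction_summary(f)
  }
  dmr_tab <- rs[significant == TRUE,
                c("region_id", "chrom", "start", "end", "pvalue"), with = FALSE]
  if (nrow(dmr_tab))
    dmr_tab[, direction := vapply(region_id, dir_of, character(1))]
  ann_smooth <- assign_dmrs(dmr_tab, features)
  ann_base <- assign_dmrs(
    base_dmrs[, c("region_id", "chrom", "start", "end"), with = FALSE],
    features)

  say("cross-method comparison")
  relaxed_ids <- rs[!is.na(pvalue) & pvalue < config$relaxed_p]$region_id
  part_smooth <- partition[region_id %in% relaxed_ids]
  part_base <- partition[region_id %in% base_dmrs$region_id]
  overlap <- if (nrow(part_smooth) && nrow(part_base))
    overlap_regions(part_smooth, part_base)
  else data.table::data.table(region_id_a = character(0),
                              region_id_b = character(0),
                              n_shared_cpgs = integer(0))
  ann_relaxed <- assign_dmrs(
    rs[!is.na(pvalue) & pvalue < config$relaxed_p,
       c("region_id", "chrom", "start", "end", "pvalue"), with = FALSE],
    features)
  g1 <- gene_min_pvalues(rs, ann_relaxed$links)
  rank_curve <- if (nrow(ann_base$dmgs) && nrow(g1)) {
    bq <- merge(data.table::as.data.table(baseline$bumps),
                unique(ann_base$links[, c("region_id", "gene_id"),
                                      with = FALSE]),
                by = "region_id")
    gene_q <- bq[, .(min_q = min(qvalue), chrom = chrom[1],
                     start = min(start)), by = gene_id]
    gene_q <- rank_by_significance(gene_q, "min_q")
    ranks2 <- stats::setNames(gene_q$rank, gene_q$gene_id)
    cumulative_average_rank(g1, ranks2)
  } else list(curve = data.table::data.table(), argmax_gene = NA_character_)
  qm <- qq_manhattan_tables(rs, config$alpha, nrow(rs))

  say("writing outputs to %s", config$out_dir)
  out <- function(f) file.path(config$out_dir, f)
  write_merged(filtered, out("merged_filtered.tsv"))
  write_regions_bed(partition, out("regions.bed"))
  data.table::fwrite(partition, out("region_membership.tsv"), sep = "\t")
  data.table::fwrite(rs, out("region_summary.tsv"), sep = "\t")
  curves <- region_curves_table(fit_res$fits, partition,
                                config$model$ci_level)
  data.table::fwrite(curves, out("region_curves.tsv"), sep = "\t")
  if (nrow(dmr_tab)) {
    bed <- data.table::data.table(chrom = dmr_tab$chrom,
                                  start = dmr_tab$start - 1L,
                                  end = dmr_tab$end, name = dmr_tab$region_id,
                                  pvalue = dmr_tab$pvalue,
                                  direction = dmr_tab$direction)
    data.table::fwrite(bed, out("dmrs.bed"), sep = "\t", col.names = FALSE)
  } else file.create(out("dmrs.bed"))
  write_dmgs(ann_smooth$dmgs, out("dmgs_smooth.tsv"))
  data.table::fwrite(baseline$bumps, out("bumps.tsv"), sep = "\t")
  write_dmgs(ann_base$dmgs, out("dmgs_baseline.tsv"))
  data.table::fwrite(overlap, out("overlap.tsv"), sep = "\t")
  data.table::fwrite(rank_curve$curve, out("rank_curve.tsv"), sep = "\t")
  data.table::fwrite(qm$qq, out("qq.tsv"), sep = "\t")
  data.table::fwrite(qm$manhattan, out("manhattan.tsv"), sep = "\t")

  mean_or_na <- function(v) if (length(v)) round(mean(v), 1) else NA_real_
  manifest <- data.table::data.table(
    field = c("counts_md5", "metadata_md5", "features_md5", "seed", "alpha",
            "gap_bp", "min_cpgs", "min_strand_depth", "max_prop_diff",
            "min_valid_cases", "min_valid_controls", "basis_df",
            "window_cpgs", "bump_cutoff", "n_perm", "relaxed_p",
            "bonferroni_threshold", "n_cpgs_retained", "n_regions",
            "n_regions_eligible", "n_dmrs_smooth", "n_dmgs_smooth",
            "n_dmrs_unannotated_smooth", "mean_cpgs_per_region",
            "mean_cpgs_per_dmr_smooth", "n_bumps", "n_dmrs_baseline",
            "n_dmgs_baseline", "mean_cpgs_per_dmr_baseline",
            "n_overlapping_pairs", "n_shared_genes", "rank_argmax_gene"),
    value = as.character(c(
      unname(tools::md5sum(config$counts)),
      unname(tools::md5sum(config$metadata)),
      unname(tools::md5sum(config$features)),
      config$seed, config$alpha, config$gap_bp, config$min_cpgs,
      config$min_strand_depth, config$max_prop_diff,
      config$min_valid_cases, config$min_valid_controls, config$spec$df,
      config$window_cpgs, config$cutoff, config$n_perm, config$relaxed_p,
      signif(thr, 6), nrow(sites), nrow(rt), sum(rt$eligible),
      length(dmr_ids), nrow(ann_smooth$dmgs), length(ann_smooth$unannotated),
      mean_or_na(rt$n_cpgs), mean_or_na(rs[significant == TRUE]$n_cpgs),
      nrow(baseline$bumps), nrow(base_dmrs), nrow(ann_base$dmgs),
      mean_or_na(base_dmrs$n_cpgs), nrow(overlap),
      length(intersect(ann_relaxed$dmgs$gene_id, ann_base$dmgs$gene_id)),
      rank_curve$argmax_gene)))
  data.table::fwrite(manifest, out("manifest.tsv"), sep = "\t")
  writeLines(c("dmrsmooth run manifest",
               sprintf("  %-28s %s", manifest$field, manifest$value)),
             out("manifest.txt"))

  invisible(list(merged = filtered, partition = partition,
                 region_summary = rs,
                 fits = if (keep_fits) fit_res$fits else NULL,
                 dmrs = dmr_tab, dmg_smooth = ann_smooth, bumps = baseline$bumps,
                 dmg_baseline = ann_base, overlap = overlap,
                 rank_curve = rank_curve, qq_manhattan = qm,
                 manifest = manifest, bonferroni = thr))
}
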