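#!/usr/bin/env Rscript
# Stage 6: cross-method concordance.
#
# CpG-level overlap between the model's relaxed (p < 0.05) regions and the
# baseline's q <= 0.05 bumps; gene-level rank agreement as a cumulative
# average rank curve; QQ and Manhattan report tables for the regional
# p-values.

suppressMessages(library(dmrsmooth))

rs <- data.table::fread("results/region_summary.tsv")
bumps <- data.table::fread("results/bumps.tsv")
part <- data.table::fread("results/region_membership.tsv")
feats <- load_features("results/data/features.bed")

relaxed <- rs[!is.na(rs$pvalue) & rs$pvalue < 0.05]
base_sig <- bumps[bumps$qvalue <= 0.05]
ov <- overlap_regions(part[part$region_id %in% relaxed$region_id],
                      part[part$region_id %in% base_sig$region_id])
data.table::fwrite(ov, "results/overlap.tsv", sep = "\t")

ann_rel <- assign_dmrs(relaxed[, c("region_id", "chrom", "start", "end"),
                               with = FALSE], feats)
ann_base <- assign_dmrs(base_sig[, c("region_id", "chrom", "start", "end"),
                                 with = FALSE], feats)
g1 <- gene_min_pvalues(rs, ann_rel$links)
shared <- intersect(g1$gene_id, ann_base$dmgs$gene_id)

bq <- merge(bumps, unique(ann_base$links[, c("region_id", "gene_id"),
                                         with = FALSE]), by = "region_id")
gene_q <- bq[, .(min_q = min(qvalue), chrom = chrom[1], start = min(start)),
             by = gene_id]
gene_q <- rank_by_significance(gene_q, "min_q")
curve <- cumulative_average_rank(g1, stats::setNames(gene_q$rank,
                                                     gene_q$gene_id))
data.table::fwrite(curve$curve, "results/rank_curve.tsv", sep = "\t")

qm <- suppressWarnings(qq_manhattan_tables(rs, n_tests = nrow(rs)))
data.table::fwrite(qm$qq, "results/qq.tsv", sep = "\t")
data.table::fwrite(qm$manhattan, "results/manhattan.tsv", sep = "\t")

cat(sprintf("overlapping region pairs (>=1 shared CpG): %d\n", nrow(ov)))
cat(sprintf("genes found by both methods: %d of %d (model, relaxed) and %d (baseline)\n",
            length(shared), nrow(g1), nrow(ann_base$dmgs)))
if (!is.na(curve$argmax_gene))
  cat(sprintf("rank concordance peaks at gene %s (running mean %.3f)\n",
              curve$argmax_gene, max(curve$curve$running_mean)))
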