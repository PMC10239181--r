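#!/usr/bin/env Rscript
# Stage 2: strand merge, concordance and coverage filters, region partition.
#
# Both strands must reach depth 3 and agree within 0.2 in methylation
# proportion; a CpG is kept when at least 6 of 9 cases and 3 of 4 controls
# remain valid; retained CpGs split into regions at gaps of 200 bp or
# more, with >= 60 CpGs required for model eligibility.

suppressMessages(library(dmrsmooth))
dir.create("results", showWarnings = FALSE)

counts <- read_counts("results/data/counts.tsv")
meta <- read_sample_meta("results/data/meta.tsv")

merged <- merge_strands(counts)
filtered <- filter_sites(merged, meta)
sites <- unique(filtered[, c("chrom", "pos"), with = FALSE])
part <- partition_regions(sites)

write_merged(filtered, "results/merged_filtered.tsv")
write_regions_bed(part, "results/regions.bed")
data.table::fwrite(part, "results/region_membership.tsv", sep = "\t")

rt <- region_table(part)
cat(sprintf("merged %d CpGs; %d retained after the 3/0.2/6-of-9/3-of-4 rules\n",
            length(unique(paste(merged$chrom, merged$pos))), nrow(sites)))
cat(sprintf("partition: %d regions, %d eligible (>= 60 CpGs), mean %.1f CpGs/region\n",
            nrow(rt), sum(rt$eligible), mean(rt$n_cpgs)))
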