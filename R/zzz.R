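# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "N", "valid", "vc", "vk", "ok", "new_region", "region_idx",
  "region_id", "n_cpgs", "eligible", "pos", "chrom", "meth", "total",
  "region", "slope", "smoothed_slope", "mean_abs_beta", "stat", "qvalue",
  "significant", "pvalue", "gene_id", "feature_class", "direction",
  "min_q", "start", "rank"))

.datatable.aware <- TRUE
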