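# dmrsmooth

Regional differential-methylation analysis for whole-genome bisulfite
sequencing (WGBS) count data, built for small case-control designs with a
continuous confounder (the defaults assume 9 cases vs 4 controls,
adjusted for age).

WGBS gives, per sample and CpG site, methylated read counts out of a
total depth. Because methylation varies smoothly along the genome,
`dmrsmooth` tests *regions* rather than single sites: retained CpGs are
partitioned into regions at inter-CpG gaps of ≥ 200 bp, and within each
region of ≥ 60 CpGs the model estimates smooth covariate-effect curves on
the logit scale,

    logit π_i(t) = β0(t) + D_i · β1(t) + age_i · β2(t),

where each β(t) is a penalized cubic B-spline in the genomic coordinate
t, π is the methylation probability of sample i at CpG t, and the counts
follow an over-dispersed binomial (multiplicative dispersion φ plus an
intra-CpG read correlation ρ estimated from the depth-dependence of the
Pearson residuals). The disease curve β1(t) is tested region-wide with a
Wald quadratic form at its effective degrees of freedom, and regions are
called differentially methylated (DMRs) under Bonferroni family-wise
control — for 8268 regions at FWER 0.05 the per-region threshold is
0.05/8268 = 6.05e-06.

The package also implements, around that core:

- strand-aware preprocessing (per-strand depth ≥ 3, strand concordance
  < 0.2, coverage in ≥ 6/9 cases and ≥ 3/4 controls);
- a two-stage bump-style baseline (per-CpG OLS slopes → 5-CpG running
  mean → mean |slope| ≥ 0.2 → q-values from 40 label permutations);
- structural gene annotation of DMRs through a 9-class feature vocabulary
  (with antisense lncRNA partners as distinct genes), yielding
  differentially methylated genes (DMGs);
- cross-method CpG-overlap and rank-concordance summaries (cumulative
  average rank curves, QQ/Manhattan report tables);
- a synthetic-data generator with known smooth effect curves, so the
  whole pipeline is testable with no external data.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study —
1370 CpGs in 7 intended regions on two chromosomes, two regions carrying
disease effects (one hypo-, one hypermethylated in cases), everything
else null:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_fit_regions.R
Rscript analysis/04_baseline.R
Rscript analysis/05_annotate.R
Rscript analysis/06_compare.R
```

What a run of those six scripts prints (seed 1):

```
simulated 1370 CpGs in 7 intended regions, 33835 strand records
merged 1370 CpGs; 475 retained after the 3/0.2/6-of-9/3-of-4 rules
partition: 7 regions, 5 eligible (>= 60 CpGs), mean 67.9 CpGs/region
fitted 5 regions; Bonferroni threshold 0.01
  DMR chr1_00001: 92 CpGs, p = 3.51e-218, phi = 1.01, direction = hypo
  DMR chr2_00002: 111 CpGs, p = 1.94e-205, phi = 1.02, direction = hyper
top DMR model-derived proportions: cases 0.355, controls 0.654 (gap 30.0 pp)
2 candidate bumps (mean |smoothed slope| >= 0.2)
  bump chr1_00001: 92 CpGs, mean|beta| = 0.295, q = 0.000
  bump chr2_00002: 111 CpGs, mean|beta| = 0.216, q = 0.013
smooth model: 2 DMRs -> 3 DMGs (0 unannotated DMRs)
baseline:     2 DMRs -> 3 DMGs (0 unannotated DMRs)
genes found by both methods: 3 of 3 (model, relaxed) and 3 (baseline)
```

Reading it: the harsh strand filters keep 475 of 1370 CpGs (attrition on
this scale is expected at ~18x per-strand depth); exactly the two regions
simulated with effects are called by both methods, with the right
directions; the model-derived group methylation averages over the top DMR
differ by 30 percentage points (cases lower — it was simulated
hypomethylated); dispersion φ ≈ 1 after the read-correlation reweighting;
and annotation links the hypomethylated DMR to its synthetic gene *and*
the overlapping antisense lncRNA, giving 3 DMGs from 2 DMRs.

All tables land under `results/` (region summaries, per-CpG curve
estimates with pointwise intervals, bumps with q-values, DMG tables,
overlap and rank-concordance curves, QQ/Manhattan tables).

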