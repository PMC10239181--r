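---
title: "Regional differential methylation from WGBS counts: model and design notes"
author: "dmrsmooth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional differential methylation from WGBS counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) yields, per sample and per CpG
site, a count of methylated reads out of a total read depth. Case-control
comparisons of methylation are more powerful at the *region* level than
site by site: methylation varies smoothly along the genome over hundreds
of base pairs, so neighbouring CpGs carry shared information, and
region-level testing drastically reduces the multiple-testing burden
(thousands of regions instead of millions of sites).

`dmrsmooth` implements a complete regional differential-methylation
workflow for small case-control WGBS designs (the defaults assume 9 cases
vs 4 controls with an age covariate):

1. strand-aware filtering and merging of cytosine counts;
2. partitioning of retained CpGs into disjoint regions;
3. a single-stage regional model with penalized smooth covariate-effect
   curves over an over-dispersed binomial likelihood, tested region-wide;
4. a two-stage "bump"-style baseline (sitewise OLS, smoothing, cutoff,
   permutation FDR) for comparison;
5. structural gene annotation of significant regions;
6. cross-method overlap and rank-concordance summaries.

A synthetic-data generator with known smooth effect curves makes every
stage testable without any external download.

## Data processing and filtering

A CpG is observed on both strands (the forward C and the reverse-strand C
of the palindromic CpG). Per sample and CpG we require:

* depth **>= 3 on each strand**, and
* strand methylation proportions differing by **less than 0.2** (strict;
  a tie at exactly 0.2 is invalid, enforced by a cross-multiplied integer
  comparison immune to floating-point rounding).

Valid records are merged (counts summed across strands). A CpG site is
retained when at least **6 of 9 cases and 3 of 4 controls** are valid;
both thresholds are plain counts and configurable for other designs. The
concordance check is applied per sample: the rule exists to catch
sample-specific strand artifacts (incomplete conversion, allelic mapping
noise), which pooling across samples would dilute.

Retained CpGs are split into disjoint regions wherever consecutive sites
are **200 bp or more** apart (the strict ">= 200" reading is used
throughout; the alternative "maximum of 200" convention differs by one
base pair and by less than one region per thousand on realistic spacing
distributions). Regions with **>= 60 CpGs** are eligible for the regional
model; smaller regions are kept — the baseline analyses all of them.

## The regional model

For sample $i$ at CpG position $t$ within one region, with disease
indicator $D_i$ and age $a_i$ (centered at the sample mean), the
methylation probability is

$$\operatorname{logit} \pi_i(t) = \beta_0(t) + D_i\,\beta_1(t) + a_i\,\beta_2(t),$$

and the methylated count is an over-dispersed binomial draw with
denominator equal to the merged depth. An optional read-error layer maps
$\pi$ to $\pi^* = \pi\,p_1 + (1-\pi)\,p_0$ before the binomial stage
($p_0$ = probability an unmethylated read is observed methylated, $p_1$
its methylated counterpart; defaults $p_0=0$, $p_1=1$ switch the layer
off, since no error rates are printed for the study conditions we
emulate).

Each curve $\beta_j(t)$ is a cubic B-spline on the bp coordinate axis
(dimension 10 per curve by default, interior knots at CpG-position
quantiles so knot density follows CpG density) with a second-order
difference penalty on adjacent basis coefficients — constants and linear
trends are unpenalized. Fitting is by penalized IRLS on the binomial
working likelihood; convergence is declared at a relative coefficient
change below `1e-8` (200 iterations maximum, `converged = FALSE` and a
withheld p-value otherwise). Regions where the linear predictor runs to
the boundary (|logit| > 12, e.g. all-zero counts) are flagged `boundary`
and still return.

### Over-dispersion

Two mechanisms are distinguished:

* a multiplicative dispersion $\phi$, estimated as the Pearson statistic
  over residual degrees of freedom, scaling all covariances;
* an intra-CpG read correlation $\rho$ (beta-binomial flavour), estimated
  by a moment equation from the depth-dependence of the Pearson residuals
  and folded into the weights as effective denominators
  $n/(1 + (n-1)\rho)$.

The second mechanism matters because read depth varies strongly across
sites (negative-binomial-like), so beta-binomial variance
$n\,p(1-p)\,(1+(n-1)\rho)$ is *not* a constant multiple of binomial
variance: a constant-$\phi$ quasi-binomial overweights deep observations
and produces anti-conservative region tests (we measured 0.09 empirical
size at nominal 0.05 under beta-binomial truth with dispersed depths,
restored to 0.054 with the reweighting). $\rho$ is estimated from the
*least-smoothed* fit on the grid, so genuine signal that a heavily
smoothed fit fails to capture cannot masquerade as over-dispersion. The
classical constant-$\phi$ quasi-binomial remains available as
`model_config(variance = "quasibinomial")`; its point estimates coincide
with binomial IRLS, which is the configuration under which the package's
fits are checked against `glm(family = quasibinomial())` to $10^{-6}$.

### Smoothing selection

A single smoothing multiplier scales all three curves' penalties
(normalized against the information matrix, so the grid
$10^{-4}\ldots10^{3}$ is problem-size invariant); it is selected on that
grid by restricted maximum likelihood (REML) of the converged Gaussian
working model, followed by a separate 1-D REML refinement of the
disease-curve multiplier. The design was genuinely open and we settled it
empirically:

* a purely shared multiplier lets the nuisance curves (baseline, age),
  which typically want heavy smoothing, drag the disease curve with them:
  pointwise interval coverage of the true disease curve dropped to ~0.83
  because ~15% of replicates flattened a real bump;
* per-curve selection by GCV restored coverage but inflated the null
  region test to 0.075 at nominal 0.05 — GCV's high selection variance on
  the *tested* curve feeds straight into the test statistic;
* REML's lower selection variance gives both: coverage 0.91 and empirical
  size 0.054 (at 0.001, 0.00125), measured over hundreds of replicates at
  the default study conditions (13 samples, 60 CpGs, depth 36,
  $\rho = 0.05$).

Degenerate configurations (constant basis `spline_spec(df = 1)` and/or
`smoothing = "fixed", lambda = 0`) reduce the model exactly to ordinary
logistic regression on pooled counts, which the test suite exploits as an
oracle anchor.

### The region test

$H_0\!: \beta_1(t) \equiv 0$ is tested by a Wald quadratic form on the
disease-curve coefficients using their Bayesian covariance
$\phi\,(X^\top W X + S)^{-1}$, eigen-truncated at rank equal to the
rounded effective degrees of freedom of the disease curve (the trace of
its block of the influence matrix), and referred to a chi-square with
that rank. The p-value is `NA` with a status flag when IRLS has not
converged. Empirical size at the study conditions is within Monte-Carlo
noise of nominal from 0.05 down to 0.001 (the range the Bonferroni rule
exercises).

Note one symmetry subtlety: swapping case/control labels negates
$\beta_1(t)$ *exactly* only in unpenalized configurations. The roughness
penalty is not invariant under the induced reparameterization
$(\beta_0, \beta_1) \to (\beta_0+\beta_1, -\beta_1)$, so penalized fits
are only approximately antisymmetric; the tests assert exactness where it
holds and near-antisymmetry elsewhere.

### Reported quantities

Pointwise intervals are normal-theory bands `estimate ± z·SE` on the
logit scale. Model-derived group proportions invert the fitted linear
predictor at a case and a control profile (age fixed at the centering
age by default), are averaged over a CpG subset, and the group difference
is reported in percentage points (control minus case: positive =
hypomethylated in cases). The Bonferroni threshold is literally
`alpha / n_regions`.

## The two-stage baseline

Stage one regresses each CpG's per-sample methylation proportion on
disease and age by OLS (slope = disease coefficient; undefined when
fewer than 2 informative samples remain in either group). Stage two
smooths the slopes with a centered 5-CpG running mean strictly within
regions, and flags a region as a candidate bump when the mean of
|smoothed slope| reaches 0.2. The smoother and window are our choices (no
smoother is named in the description we follow); a running mean is the
simplest smoother with the required region-mean-conservation property,
and the filter is applied to the *smoothed* slopes, consistent with the
two-stage logic of smoothing before thresholding. Significance comes from
genome-wide label permutations (group sizes fixed, 40 by default): with
observed statistic $s$,

$$q(s) = \frac{\#\{\text{pooled null statistics} \ge s\}}
             {n_{\text{perm}} \cdot \#\{\text{observed statistics} \ge s\}},$$

clipped to $[0,1]$ and monotonized so $q$ never increases with $s$. An
explicit permutation-set argument supports exhaustive enumeration in tiny
designs, which the tests compare against a brute-force oracle.

## Annotation and comparison

Gene features come from a BED6+2 file with a fixed 9-class vocabulary
(upstream 1–5 kb, promoter, gene body, 5' UTR, exon, first exon, intron,
3' UTR, intergenic). A DMR links to a gene when it overlaps >= 1 bp of
any non-intergenic feature of that gene; overlap is strand-blind (counts
were strand-merged upstream), so a DMR across a sense gene and its
antisense lncRNA yields two distinct gene records; DMRs touching only
intergenic space are "unannotated". DMR direction over a region is read
from the CpGs whose pointwise interval excludes zero (`hyper`, `hypo`,
`mixed`, or `none`).

Cross-method comparison treats two regions as overlapping when they share
at least one CpG position. Gene-level agreement walks method 1's genes in
ascending minimum region p-value and, for each gene present among method
2's $M$ ranked genes, scores the normalized reversed rank
$(M - r + 1)/M$; the curve is the running mean over matched genes so far
(unmatched genes emit no point and do not enter the denominator — the
running mean should reflect agreement where agreement is measurable), and
its argmax marks the strongest agreement. QQ report tables pair sorted
p-values with uniform quantiles $(i-0.5)/n$ and a 95% band from beta
order-statistic quantiles.

## The synthetic-data generator

The generator emulates the targeted study design: 9 cases vs 4 controls;
ages uniform on 20–80 years; per-strand depth negative-binomial with mean
18 (≈ 36 merged, matching the reported median retained depths of 34–39)
and dispersion 0.3; intra-CpG read correlation 0.05 realized as a shared
Beta-distributed latent methylation probability per sample × CpG (the
simplest count-valid over-dispersed binomial, which also induces
realistic between-strand correlation); read-error layer off by default;
5% of strand records dropped at random; CpG layouts with within-region
spacings far below and between-region gaps far above the 200 bp partition
threshold, so the intended structure is exactly recoverable. Randomness
derives from one master seed through per-sample streams, so adding
samples never perturbs existing samples' draws.

What it does **not** emulate: genome-scale CpG spacing heterogeneity
(CpG islands vs deserts), spatial correlation of depth, bisulfite
conversion chemistry, alignment artifacts, cell-composition effects, or
sex chromosomes. Passing tests therefore demonstrate statistical
correctness of the machinery under a faithful small-scale count model,
not robustness to every artifact of real methylomes.

A note on realism worth knowing: under these study conditions the
3/0.2/6-of-9/3-of-4 filters retain only ~30–40% of simulated CpGs — the
0.2 strand-concordance rule is genuinely harsh at ~18x per-strand depth
(the binomial SD of a strand proportion difference is ~0.17 at
intermediate methylation). This mirrors the scale of attrition reported
for the real analysis and means synthetic layouts must be dense if
post-filter regions are to clear the 60-CpG eligibility bar.

## Problem sizes and numerical choices

The shipped analyses and checks run at desk scale, chosen as the smallest
sizes at which the measured quantities are statistically meaningful: ~1400
simulated CpGs in 7 regions for the end-to-end workflow; 1000 replicates
for test size at $\alpha = 0.05$; 100 replicates per depth for the
recovery ordering; 400 replicates × 50 regions for family-wise error;
200 replicates for interval coverage. Headline counts of the genome-scale
analysis this mirrors (8268 regions and descendants) depend on
unavailable patient data and are not reproduced.

Other numerical choices: penalties are normalized by the initial
information scale before the multiplier grid; a ridge of
$10^{-9}\,\overline{\mathrm{diag}}$ stabilizes the penalized information
Cholesky; fitted probabilities are clamped to $[10^{-10}, 1-10^{-10}]$;
ranking ties break by genomic order so all outputs are deterministic;
p-values of exactly 0 (chi-square underflow for extreme effects) are
clipped to the smallest representable double in report tables, with a
warning.

## Known limitations

* The region test conditions on the selected smoothing; selection
  uncertainty is not propagated (mitigated, not removed, by REML).
* $\rho$ is a single per-region constant; real intra-CpG correlation may
  vary along the region.
* The baseline's candidacy unit is the pre-partitioned region, not
  threshold-crossing sub-segments within it; sub-region bumps are
  averaged over the whole region.
* One smooth confounder (age) is supported; random effects and cell-type
  deconvolution are out of scope.
* Pointwise (not simultaneous) intervals: ~0.91 average pointwise
  coverage at sharp features, with the usual across-the-function
  interpretation of Bayesian smoothing bands.

## A minimal session

```{r example}
library(dmrsmooth)

cfg <- sim_config(seed = 1, chrom_layout = list(
  list(chrom = "chr1", cpgs = c(260L, 260L), spacing = c(2L, 12L), gap = 500L)))
pos <- simulate_positions(cfg)
meta <- simulate_metadata(cfg)
# a hypomethylation effect in the first intended region only
b1 <- ifelse(pos$region == "chr1_r1", -2, 0) *
  exp(-0.5 * ((seq_len(nrow(pos)) %% 260 / 260 - 0.5) / 0.25)^2)
eff <- make_true_effects(pos, beta0 = 0.4, beta_disease = b1,
                         beta_age = 0.004)
counts <- simulate_counts(pos, meta, eff, cfg)

merged <- filter_sites(merge_strands(counts), meta)
part <- partition_regions(unique(merged[, c("chrom", "pos")]))
fits <- fit_all_regions(merged, meta, part)
fits$summary
```

The numbered scripts under `analysis/` run the same stages as a
reproducible workflow, writing all tables under `results/`.
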