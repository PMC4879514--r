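---
title: "Measuring expression divergence between closely related species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring expression divergence between closely related species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprdiverge)
```

This vignette is the package's own account of its methods: the models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where several were defensible.

## The scientific setting

Two species that diverged recently — on the order of a million years — still
share most of their expression program. Organs differ from each other far
more than species do, so naive clustering of multi-organ samples is
dominated by organ identity. Against that background, the questions this
package answers are quantitative: per gene and organ, how large is the
between-species expression difference relative to the within-species
variation; which genes exceed a permutation null; how divergence relates to
pleiotropy proxies and sequence evolution; and which genes show qualitative
presence/absence differences, possibly caused by structural variants.

The expected inputs are a genes-by-samples FPKM matrix with sample metadata
(individual, species, organ, sex), per-gene covariate tables (upstream-window
F_ST, lineage dN/dS, protein-interaction counts, length, GC, position), and
per-individual windowed read-depth tracks for the deletion screen. All are
plain TSV; coordinates are 0-based half-open throughout (BED convention),
and missing covariates are explicit (`.` in files, `NA` in memory), never
zero — analyses drop incomplete genes pairwise, per analysis.

## zFPKM normalization and expressed-gene calls

FPKM corrects for length and depth but not for the shape of each library's
expression distribution. The zFPKM transform anchors each sample at the mode
of its log2-FPKM density (`mu_peak`) and scales by the spread of the right
half-distribution: `sigma` is the root-mean-square deviation of the values
above the mode, i.e. a half-Gaussian fit to the expressed population; the
left shoulder, contaminated by unexpressed genes, is ignored. Genes with
FPKM = 0 carry a `-Inf` sentinel and can never be called expressed.

Numerical choices:

* Kernel density: Gaussian kernel, Silverman's rule-of-thumb bandwidth, 512
  grid points over the data range ± 3 bandwidths.
* **Mode refinement.** The raw argmax of a kernel density is a noisy mode
  estimator (sampling SD ≈ 0.3 log2 units at 10,000 genes). `mu_peak` is
  therefore refined by an iterated trimmed mean: the mean of the values
  within ± 1.5 right-tail sigma of the current estimate, iterated to a fixed
  point (a uniform-kernel mean shift). For a locally symmetric peak this is
  unbiased with SD ≈ 0.03; a skewed shoulder biases it slightly, but the
  bias is shared by all samples of a study, which preserves the cross-sample
  comparability the transform exists for. Re-fitting already-normalized
  values finds `mu_peak ≈ 0` and `sigma ≈ 1` (tested).
* Expressed cutoff: `z ≥ 0.125` by default, configurable. The boundary is
  inclusive. 0.125 is kept as the package default deliberately;
  mode-anchored pipelines in the literature differ in their recommended
  threshold, so the argument is exposed rather than second-guessed.
* Samples need at least 100 genes with FPKM > 0 for a stable fit
  (configurable); fewer is an error, not a warning.

One property worth knowing: because the anchor is the density mode, any
expression shift shared by the majority of genes in a sample is absorbed by
the normalization. Species-level divergence is therefore measured *relative
to the transcriptome bulk* — appropriate when divergence affects a minority
of genes, misleading if half the transcriptome moved the same way.

## Expression P_ST

For one gene in one organ (one sample per individual), expression is
decomposed as species (between) plus individual-within-species (residual)
variance after adjusting for sex:

* **Estimator.** REML for the one-random-factor model, computed by
  root-solving the analytic REML score equation for the variance ratio
  (block algebra makes each evaluation O(n)). This localizes the optimum to
  ~1e-13, where a value-based optimizer stalls at ~1e-6 because the profile
  likelihood is flat near its maximum. On balanced designs the REML solution
  coincides exactly with the ANOVA method-of-moments estimator
  `σ²_b = (MS_between − MS_within)/n₀`; the package's method-of-moments
  engine (`engine = "anova"`) adopts the matching boundary convention —
  a negative between-component is set to zero and the within-component
  re-estimated under the species-free model — so the two engines agree
  everywhere on balanced data (tested to 1e-6; cross-checked against lme4).
* **Sex.** Sex enters as a fixed covariate by default: with two levels a
  random effect is weakly identifiable. A literal random-effects treatment
  is available (`sex_adjust = "random"`); single-sex organs (testis, ovary)
  drop the term automatically.
* **Statistic.** `P_ST = c·σ²_b / (c·σ²_b + 2σ²_w)` with the `c/h²`
  multiplier exposed (`scaling_ratio`, default 1) because the P_ST
  literature varies in how heritable/additive the trait is assumed to be.
  Truncation at zero keeps P_ST in [0, 1]; both components zero gives `NA`
  with a warning.
* **Null.** Permutations reassign species labels across the individuals of
  the organ, keeping each individual's sex attached; this is the natural
  null of "no species effect" when individuals are the exchangeable units.
  Each gene gets a deterministic substream derived from (seed, organ, gene
  row index), so results are independent of gene processing order and of
  subsetting. If fewer distinct label assignments exist than requested
  replicates, all are enumerated (with a warning) — this happens for gonads
  at five individuals per species (252 assignments) or fewer.
  P-values use the resampling correction `p = (b+1)/(m+1)`, never exactly
  zero, and are BH-adjusted across the genes of one organ scan. Inside the
  permutation loop the method-of-moments engine is used: on these balanced
  designs it is the REML answer at a fraction of the cost, and the observed
  statistic is computed by the same engine as its null.
* Genes enter an organ's scan only if expressed in **every** sample of that
  organ in both species; anything less mixes detection noise into the
  variance components.

## Organ specificity

`τ = Σ (1 − x_i/x_max)/(N − 1)` over organ means. Means are taken per
species on the linear scale (2^zFPKM, sentinels contributing zero) because τ
assumes non-negative intensities; a zFPKM-clipped variant is available
(`scale = "zfpkm"`). Breadth is `1 − τ`. τ is invariant under rescaling the
mean vector, and adding a zero-expression organ can only increase it (both
tested as properties).

## Correlates

Spearman correlations (via `stats::cor.test`; t-approximation, exact for
small tie-free n) of three responses — P_ST, σ²_b, σ²_w — against
interaction counts, τ, dN/dS and upstream F_ST, BH-adjusted as **one**
family across the whole organ × target × response grid. The dN/dS filter
removes genes with `dS > 2` or `dN/dS > 3` (saturation, alignment error).
High-F_ST contrasts use Mann–Whitney tests on P_ST and chi-square tests of
high-P_ST enrichment over F_ST cutoffs 0.3–0.8 and P_ST cutoffs 0.05–0.3;
positional checks compare the DE proportion on the sex chromosome (Z)
against autosomes and correlate per-chromosome DE proportion with
chromosome size. Raw and adjusted p-values are both reported throughout.

## Ordination

Euclidean distances between samples on zFPKM values, over the genes with
finite values in every sample (listwise deletion of sentinel-carrying
genes). NMDS is Kruskal's: classical metric MDS provides the starting
configuration, then iterative stress-1 minimization (via `MASS::isoMDS`,
the standard implementation; stress reported on [0, 1]). The seed only
perturbs exact ties in the input distances, so results are deterministic.
Scree tables report stress per dimensionality with an advisory elbow
(largest second difference) that is never applied silently. Per-axis ANOVA
uses type-II sums of squares (`car::Anova`) for organ, sex, species and
their interactions; interactions are dropped with a warning when the design
aliases them (single-sex organs alias organ × sex). Organ-versus-species
clustering strength is quantified by mean silhouette widths on the
configuration.

## Presence/absence and the deletion screen

A gene is unique to one species when at least five *individuals* (not
samples) of that species express it somewhere and the other species shows
zero expressed calls anywhere. Counting individuals guards against
single-library artefacts; a flag (`same_organ`) optionally requires the
five individuals to share an organ. The deletion screen looks for runs of
at least `min_region_windows` consecutive windows (default 5, i.e. 1 kb at
200-bp windows) with zero depth in every individual of one species and
positive depth in every individual of the other; windows that are zero in
everyone are assembly gaps and are excluded as evidence, as are windows
with missing data. Fixation is required: a single discordant individual
kills a call.

## The synthetic-data generator

The generator emulates the sampling design of a two-species, multi-organ
population RNA-seq study: nine organs (brain, embryo, kidney, liver, lung,
muscle, ovary, skin, testis), ten individuals per species (five of each
sex), gonads sampled only in the matching sex (halving their n). Embryo is
treated as a ninth organ of the same individuals — real studies sample
separate embryos; the simplification keeps the individual-level permutation
design uniform. Expression follows, on the log2 scale,

    mu_g + a_go + delta_g·I(species B) + beta_g·I(male) + b_gs + eps

with gene baselines `mu_g ~ N(4, 2²)`, gene × organ effects
`a_go ~ N(0, 2²)`, species effects `b_gs ~ N(0, σ²_b)`, residuals
`N(0, σ²_w)`, then FPKM = 2^value with a detection floor (values below −4
log2 become zero). Genes fall into four evolutionary regimes
(stabilizing / neutral / directional / balancing, default proportions
0.70/0.20/0.05/0.05) that set (σ_w, σ_b) per gene; directional genes add a
fixed shift `delta` with a **random sign** per gene — selection pushes
different genes in different directions, and a one-sided net shift would
largely be absorbed by the mode-anchored normalization anyway.

Three deliberate structural choices:

* **Per-gene sigma jitter, correlated across components.** Regime sigmas get
  lognormal jitter (sdlog 0.25) with correlation 0.5 between the σ_b and
  σ_w jitters. Real data show within-species variance and between-species
  divergence to be positively related (drift makes divergence scale with
  standing variation; stabilizing selection shrinks both), and rank-based
  analyses degenerate if the truth takes only four values. The default
  stabilizing and neutral regimes share the same σ_b/σ_w ratio for the same
  reason; the regimes differ in magnitude, directional and balancing genes
  in ratio.
* **Exact presence/absence ground truth.** Only planted genes may be fully
  absent in one species. Because the expressed-call threshold is relative to
  each sample's realized density mode, no absolute-scale rule can guarantee
  this; the generator therefore audits its own realization with the
  package's zFPKM calls and lifts offending genes clear of the detection
  boundary, iterating to a fixed point. Lifts shift both species equally,
  preserving expression differences. Real data of course do contain such
  borderline genes — that is exactly why presence/absence candidates need
  orthogonal (e.g. coverage) evidence — but a generator with ambiguous
  ground truth cannot validate a detector.
* **Covariates via a Gaussian copula.** Interaction counts (negative
  binomial marginals), upstream F_ST (Beta with mean 0.26, matching
  genome-wide differentiation between young species pairs) and dN/dS
  (gamma) are coupled to the true variance components through normal scores,
  so a target Spearman correlation (default ρ = −0.3 between interactivity
  and σ²_w, the pleiotropy-constraint pattern) is planted without
  distorting the marginals. A small fraction of covariate entries is
  missing, as in real ortholog-limited tables.

The coverage generator plants a 20-kb deletion (windows exactly zero in
every individual of one species) on a 100-kb scaffold at 200-bp windows,
Poisson(15) depth elsewhere (~15× genomes), a 13-exon gene model with 11
exons inside the deletion, and an assembly-gap interval that is zero in
everyone as a negative control for the screen's gap exclusion.

What passing tests on this generator do **not** show about real data:
library-level technical batch effects, count-level overdispersion,
mapping biases, genuinely ambiguous borderline expression, and partial or
polymorphic deletions are all absent. The generator validates the
statistical machinery, not the upstream quantification.

## Problem sizes and runtime

The test suite and the acceptance script size their simulations to run on a
single CPU in a few minutes total: null and power scans use one organ,
500–3000 genes and 200–500 permutations (per-gene nulls are vectorized over
permutations); variance-component recovery uses 500 genes at 50 individuals
per species; ordination uses 6 organs × 6 individuals × 2 species × 400
genes. A full default-design pipeline (9 organs, 160 samples, 1000 genes,
m = 500) runs in well under a minute.

## Known limitations

* P_ST with two species gives the between component a single degree of
  freedom; per-gene σ̂²_b is noisy by construction (CV ≈ √2) and only means
  over many genes are well determined.
* The permutation null assumes individuals are exchangeable across species
  within an organ; confounded designs (e.g. species sequenced on separate
  lanes) violate this and nothing in the package can detect it.
* The c/h² scaling of P_ST is not estimable from expression data alone;
  conclusions should be checked across a range of `scaling_ratio` values.
* The deletion screen requires fixation and complete coverage; polymorphic
  or heterozygous deletions are out of scope.
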