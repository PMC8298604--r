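---
title: "Methods: differential expression, co-expression and transcriptional age in txage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, co-expression and transcriptional age in txage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txage)
```

## Scope

`txage` analyses a case/control bulk RNA-seq cohort — the motivating setting
is PBMC transcriptomes from people with major depressive disorder (MDD,
stratified into treatment-resistant, treatment-responsive and untreated
groups) and healthy controls (HC) — through five linked stages:

1. a negative-binomial (NB) Wald differential-expression engine;
2. a marginal screen of clinical covariates for confounding;
3. an empirical false-positive null built from repeated differential
   expression on randomised case/control labels;
4. co-expression clustering via a topological overlap matrix (TOM) with
   metagene group tests;
5. a transcriptional biological-age score with a regression-residual
   asymmetry test.

A seeded NB count simulator with a ground-truth ledger makes every stage
testable end to end without external data.

## The differential-expression engine

For gene $g$ and sample $j$ with raw count $K_{gj}$, the model is

$$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
\log \mu_{gj} = \log s_j + x_j^\top \beta_g,$$

with sample size factor $s_j$, gene dispersion $\alpha_g$
(so $\mathrm{Var}\,K = \mu + \alpha\mu^2$) and a design $x_j$ holding an
intercept, optional adjustment covariates and the contrast indicator. The
contrast coefficient divided by $\ln 2$ is the reported log2 fold change;
positive means higher expression in the second-listed level (binary
contrasts) or the upper quartile (continuous covariates contrasted as lowest
vs highest quartile, with the linear-interpolation quantile convention and
ties included on both sides of the cuts). The Wald statistic
$\beta/\mathrm{se}(\beta)$ is referred to the standard normal, two-sided.

This is a deliberate simplification of the full DESeq2-style machinery: no
independent filtering beyond the stated coding/mean-count rule, no
fold-change shrinkage, and a normal-tail Wald p. The downstream procedures
only need a calibrated (p, log2FC) table, and the engine's type-I behaviour
is checked directly by simulation in the test suite.

Key choices:

* **Normalisation** is plain median-of-ratios: reference genes are those
  with strictly positive counts in every sample, and
  $s_j = \mathrm{median}_g\, K_{gj} / (\prod_{j'} K_{gj'})^{1/n}$. No
  pseudo-reference fallback is attempted; a matrix with no all-positive gene
  is an error. Size factors are defined up to a common scale; only their
  ratios matter downstream.
* **Dispersions** are method-of-moments estimates on normalised counts,
  $\hat\alpha_g = \max\{10^{-8}, (s^2_g - \bar\mu_g)/\bar\mu_g^2\}$, shrunk
  halfway (weight 0.5) toward a mean-dispersion trend $a_0 + a_1/\bar\mu$.
  The trend is fitted to *binned medians* of the raw estimates (20 rank bins
  on the mean axis) rather than by least squares over genes: genes carrying
  strong real effects inflate their marginal moment estimate, and a
  non-robust trend fit propagates that inflation to every gene, visibly
  over-conservative in null simulations. Estimation is marginal (no design
  information), which over-estimates dispersion for genes with strong
  effects — a conservative direction.
* **Outliers**: per-observation Cook's distances are computed from the
  final IRLS weights, $D_{gj} = r^2_{gj} h_{gj} / (p(1-h_{gj})^2)$ with
  Pearson residuals under the NB variance; a gene whose maximum exceeds the
  cutoff (default 0.2) is flagged and excluded from testing. Flagged genes
  are also excluded from the Benjamini–Hochberg family, mirroring
  excluded-from-testing semantics. The 0.2 cutoff is aggressive; one side
  effect, verified in the tests, is that genes dominated by a strong shared
  latent factor can be flagged in label-randomised comparisons — their
  factor excursions look like single-sample outliers. The cutoff is a
  parameter (`Inf` disables flagging).
* **Multiplicity**: Benjamini–Hochberg is implemented directly (step-up,
  cumulative minimum from the largest p, capped at 1, NA passthrough) and is
  verified in the tests against both `stats::p.adjust` and a brute-force
  enumeration of the step-up definition.
* **Fitting**: per-gene iteratively reweighted least squares with the
  dispersion fixed. For the ubiquitous single-binary-covariate design
  (intercept + indicator) the IRLS normal equations have a closed 2×2
  solution, which is vectorised across all genes simultaneously; general
  designs use a per-gene QR path. The two paths implement the same model and
  their agreement is itself a test. Convergence is declared at a relative
  coefficient change below 1e-8 (at most 50 iterations); non-convergent or
  degenerate (all-zero, unstable-SE) genes are reported untested rather
  than guessed at.

## Confounder screening

Each covariate in the panel is screened *marginally*: a two-group DE for
binary covariates, lowest-vs-highest age-style quartile DE for continuous
ones, no mutual adjustment. A covariate is flagged when strictly more than 5
genes reach adjusted p < 0.01. Marginal screening is a known statistical
limitation (a screen, not causal confounder discovery), and multi-level
categorical covariates are skipped with a warning since no aggregation rule
is defined for them. Size factors and dispersions do not depend on the
covariate labels and are computed once per screen.

## The randomisation null

Samples are repeatedly partitioned uniformly at random into pseudo-case and
pseudo-control groups of the cohort's real sizes (44 vs 187 by default), and
the full DE contrast is run on each partition with no adjustment covariates.
Reported are, per adjusted-p threshold, the median and maximum number of
significant genes across iterations — the expected false-positive load — and
per gene the mean raw p across iterations. The k genes (default 50) of
smallest mean p are the *recurrent false positives*; ties are broken by
lexicographic gene id so the selection is deterministic. Their enrichment in
user-supplied gene sets is tested with a one-sided hypergeometric
over-representation test against an expressed-gene background, with BH
adjustment across sets. One master seed spawns per-iteration seeds, so runs
are reproducible and the partition depends only on the sample-id *set*, not
its order.

## Co-expression clustering

Expression for this stage is size-factor-normalised counts, batch-corrected
by per-gene batch-mean centring (an additive correction only — it removes
batch shifts, not batch-specific variance). Genes must be well expressed
(mean > 10) with coefficient of variation below 0.15. The network is the
unsigned TOM on $a_{ij} = |\mathrm{cor}(g_i,g_j)|^\beta$:

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}}.$$

Average-linkage hierarchical clustering on $1-\mathrm{TOM}$ is cut at height
0.95 and clusters below 50 genes are discarded. The soft-threshold default
is $\beta = 6$, the usual unsigned-network choice. $\beta = 1$ is unsound
here: for uncorrelated genes the sample correlation scales like
$1/\sqrt{n}$, so at a few hundred samples the background TOM sits near 0.05
and null-pair dissimilarities concentrate exactly at the 0.95 cut, making
the partition a coin flip. With $\beta = 6$ the null-pair overlap is driven
to zero while strongly correlated blocks survive; block recovery is verified
against the simulator's ground truth with the adjusted Rand index.

Each surviving cluster is collapsed to a metagene: genes are z-scored across
samples (sample sd, $n-1$), zero-variance genes are excluded with a warning
rather than failing the cluster, and the metagene is the per-sample mean of
member z-scores (grand mean ~0 by construction). Group differences use the
unpaired two-tailed Welch t-test (the unequal-variance form is the robust
default; a pooled-variance switch is provided) with BH adjustment across
clusters and a reported — not asserted — significance threshold of 0.25.

## Transcriptional biological age

The age signature is built from a lowest-vs-highest age-quartile DE with no
adjustment covariates: genes passing an adjusted-p and an absolute-log2FC
cutoff enter with the sign of their age association. Scoring uses
size-factor-normalised counts on a log2(x+1) scale — uncorrected for
covariates or batch, matching the "raw but outlier-capped" convention — with
values winsorised at mean ± 3 sd per gene. The winsorisation bounds come
from the input's own moments in a single pass; a second application can in
principle clip slightly further (the bounds shrink), so the operation is
idempotent only when the first pass capped nothing. Each signature gene is
z-scored across **all samples jointly** — joint scaling is the only choice
that makes per-sample means comparable across groups — the sign is inverted
for genes down-regulated with age, and a sample's biological age is the mean
sign-aligned z-score.

The (adjusted-p, |log2FC|) cutoffs are chosen by grid search (defaults
p ∈ {0.01, 0.05, 0.1}, lfc ∈ {0, 0.3, 0.6, 1.0}, bracketing the
conventional p < 0.05, |log2FC| > 0.6 choice) to maximise the Spearman
correlation between biological and chronological age; ties prefer fewer
genes, then the smaller p cutoff. A minimum signature size of 10 guards
against spurious perfect correlations from tiny signatures. Spearman is the
Pearson correlation of mid-ranks with the t approximation for p.

The asymmetry test fits ordinary least squares of score on age over **all
samples pooled** (one line, as in a single-panel scatter; fitting on
controls only would change the null hypothesis), counts per group the
samples above and below the line — a residual of exactly zero counts as
below, an arbitrary but fixed and documented tie rule — and tests the 2×2
table with a two-sided Fisher exact test. The Fisher p enumerates the
hypergeometric support and sums point probabilities no larger than the
observed one within relative tolerance 1e-7. Above/below counts are
invariant to affine rescaling of the scores, since the regression absorbs
it.

## The synthetic cohort generator

`sim_config()` defaults encode the cohort the analyses assume: 44 HC, 94
treatment-resistant, 47 treatment-responsive and 46 untreated samples (231
total), 2,000 genes, ages uniform on 25–50 years. Counts are NB with
log-normal dispersions (median 0.05, a typical bulk RNA-seq scale),
uniform baseline log2 means on [3, 9], and uniform size factors on
[0.7, 1.4]. Planted structure:

* 500 age genes at ±0.5 log2FC per decade of *effective* age (half up, half
  down). Parameterising per decade keeps planted effects on the scale of a
  lowest-vs-highest age-quartile contrast.
* covariate effects: sex (100 genes, 1 log2FC), BMI (100 genes, 0.5 log2FC
  per population sd), batch (100 genes, 0.5 log2FC) — age, sex and BMI as
  the dominant clinical signals, batch as the technical one.
* co-expression blocks (2 × 60 genes by default) sharing a standard-normal
  per-sample latent factor entering the log2 mean with configurable loading;
  one knob that produces block-correlation structure.
* an ageing offset (default 0) added to the effective age of non-HC samples
  only, while metadata records chronological age — exactly the alternative
  hypothesis of the asymmetry test.

Non-coding labels (10% of genes) are assigned only among effect-free genes
so that planted truths survive the protein-coding filter; the fraction
exists to exercise the filter, not to model biotype biology. The generator
emulates the *statistical* structure the pipeline assumes — NB marginals,
covariate-driven log-linear effects, low-rank co-expression — and not
library-preparation artefacts, GC or length bias, compositional extremes, or
correlated clinical covariates. Passing tests therefore demonstrate that the
procedures recover the structure they model, not that real PBMC data satisfy
that model.

One caveat the tests surfaced: when planted blocks carry a very strong
loading and make up a large share of all genes, the median-of-ratios factors
partially absorb the block factor, inducing weak spurious correlations in
unrelated genes. At realistic block shares this is negligible, and the
default loading of 1 is used for recovery checks.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on generated data at
the cohort scale (2,000 genes × 231 samples) for single-run checks, with
repeated-seed calibration experiments (up to 1,000 pipeline replicates for
the size of the asymmetry test, 200 for its power) made affordable by the
vectorised IRLS fast path. Exact-arithmetic components are verified against
brute-force oracles: the Fisher test against direct `lchoose` enumeration
for every 2×2 table with total at most 40, BH against its step-up definition
for all vectors of length ≤ 6 over a p-grid, TOM against a double-loop
implementation, and the hypergeometric ORA against subset enumeration for
populations of at most 12.

Numerical conventions collected in one place: means are clamped to
[1e-10, 1e12] inside IRLS; the dispersion floor is 1e-8; quantiles use the
linear-interpolation convention; binary contrast levels order
lexicographically with the second level as "treatment" unless overridden;
residual ties count as below the line; recurrent-false-positive ties break
by gene id; pipeline manifest digests are computed on canonicalised results
(numeric content rounded to 7 significant digits, sorted by stable ids) so
they are invariant to the sample order of the inputs.

## Known limitations

* The engine's Wald p is a normal-tail approximation with a plug-in
  dispersion; no likelihood-ratio test or fold-change shrinkage is offered,
  and no exact replication of any published tool's p-values is attempted.
* Confounder screening is marginal and cannot separate correlated clinical
  covariates.
* The batch correction is additive mean-centring only.
* The co-expression stage omits the wider WGCNA feature set (scale-free-fit
  soft-threshold selection, eigengene modules, dynamic tree cut).
* The biological-age score is a signature mean, not a calibrated clock in
  years; comparisons with epigenetic or published transcriptomic clocks are
  out of scope.
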