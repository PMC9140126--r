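---
title: "Methods: monotone expression across ordered tumor stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monotone expression across ordered tumor stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(monostage)
```

This vignette is the package's account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The stage-continuum model

Bladder cancer is staged NAU < Ta < T1 < T2 < T3 < T4, from
non-malignant adjacent urothelium to distant invasion. The package's
central screen asks, per gene, whether the direction *and ordering* of
change is consistent along that axis. Two nested filters operate on a
per-stage differential table (Mann–Whitney U against NAU, fold change
`fc = mean(stage) − mean(NAU)` on the log2 scale — a difference of
means, never a ratio):

* **CDEG**: p < α (default 0.05, deliberately unadjusted) in all five
  stage comparisons, with one fold-change sign throughout. The screen
  declines multiple-testing correction by design: the five-fold
  significance requirement and the concordance constraint are already a
  stringent conjunction, and correcting each comparison would trade
  Type-I control it does not need for Type-II error it cannot afford.
* **Monotone**: a CDEG whose fc sequence over Ta…T4 is strictly
  increasing with all values positive (or strictly decreasing, all
  negative). Strictness is the default reading of "continuously
  larger/smaller": non-strict ties would admit flat profiles; a
  `strict = FALSE` switch exists because ties in discretized data are
  conceivable.

The same machinery is reused verbatim for pathway scores, regulon
activities and cell-type fractions (`monotone_pathways()` simply calls
the gene-level screen on score rows; a shared code path asserted by
test).

### Mann–Whitney details

Exact two-sided p-values are computed by full enumeration of group
labelings when the smaller group has ≤ 8 observations, at most 25% of
pooled values are tied, and the labeling count `choose(N, min)` is
below 2·10⁵ (the cap keeps one-tiny-versus-huge comparisons bounded);
enumeration on pooled ranks handles ties naturally. Otherwise the
normal approximation with tie correction and continuity correction is
used. A completely tied comparison returns p = 1.

## Synthetic cohorts: what they emulate and what they do not

`simulate_cohort()` is the package's study-conditions generator, not a
tuning knob. Defaults: 6 conditions × 30 samples, 2000 genes, 100
monotone-up and 50 monotone-down planted genes with a 0.5 log2
per-stage mean increment, unit Gaussian noise, and 12 batches crossed
with stage carrying additive N(0, 0.5²) location shifts (an optional
multiplicative component mirrors the location/scale model the
correction estimates; a `confounded` flag produces the pathological
nested design). Baseline gene means are N(7, 1.5²) log2 units, a
realistic microarray intensity scale. Survival is exponential with
hazard h₀·exp(β·score) tied to a planted standard-normal score
*independent of stage*, so the claim that a signature carries
prognostic value beyond stage is testable; censoring is independent
(each subject censored with probability `censor_rate` at a uniform time
before its event) plus administrative censoring at 120 months.

The generator does **not** emulate probe-level noise, intensity
saturation, correlated gene modules within a condition (step 5 of the
analysis workflow plants its own latent-factor modules for exactly that
reason), or stage-confounded batch composition. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
additive model, not robustness to every failure mode of real
microarray compendia.

Two honest consequences of these fixed conditions, measured by the
acceptance suite and left as they fall:

* At a 0.5 log2/stage effect with unit noise and 30 samples per
  condition, the Ta-vs-NAU Mann–Whitney test has ≈ 0.44 power, which
  caps full-screen sensitivity near 0.4 (false-discovery proportion
  stays ≈ 0). Sensitivity ≥ 0.9 would require roughly double the
  per-stage effect or sample size.
* The five stage tests share the single NAU group, so under a global
  null the per-gene CDEG probability is ≈ 6·10⁻⁴ — orders of magnitude
  above the α⁵·2⁻⁴ independence value; a 2000-gene null cohort
  typically yields one to a few CDEGs, not zero.

## Harmonization

`combat()` implements the canonical parametric empirical-Bayes
location/scale correction: per-gene standardization with
covariate-adjusted means and pooled (1/n) variance; per-batch additive
(γ) and multiplicative (δ²) effect estimates; normal and inverse-gamma
priors with method-of-moments hyperparameters; iterated conditional
posterior updates (tolerance 1e-4, max 100 iterations);
back-transformation. The implementation agrees with the reference
Bioconductor implementation to ~1e-6 on shared fixtures.

Choices: parametric priors only (the method is named without variants);
the condition label is protected as a covariate *by default* — the
source analyses report stage variability surviving correction, which is
only guaranteed when the design protects it — with disabling possible;
no reference-batch mode (all batches adjust to the grand mean). A
single batch passes through unchanged. Perfect batch–covariate
confounding is detected via design rank and rejected naming the pair.

Two numerically honest properties documented rather than idealized:
shrinkage leaves the residual *empirical* batch-mean gap at the
sampling-noise level (EB removes the estimated systematic effect, not
per-gene noise), and a second pass drifts values by ~1e-2 — the
re-shrinkage of per-batch variances toward the prior is not a fixed
point; the reference implementation drifts identically.

## Pathway and regulon scores

`ssgsea()` implements the single-sample running-sum variant: genes
ranked per sample (average ranks on ties), walked in decreasing
expression order; the score is the sum of differences between the
rank-weighted (exponent α = 0.25) in-set CDF and the uniform out-of-set
CDF, normalized by the range of the running walk. This variant was
chosen over kernel-density alternatives because it is a single
deterministic formula checkable by direct summation; the exponent and
normalization are parameters, not constants of nature. Scores depend on
a sample's values only through ranks (tested as exact invariance under
`2^x`). Rank-based scoring is compositional: if a large fraction of
genes moves with stage, decoy-set scores drift too — at the default 7.5%
planted fraction this effect is negligible, and the tests pin that
regime.

Regulon activity is the mean over targets of sign × z-score (z across
samples) — a deliberately linear, VIPER-flavored summary chosen because
the upstream resource supplies signs, not a formula. The stromal score
is the ssGSEA score of a user-supplied stromal panel; it ranks samples
by relative stromal transcript enrichment and makes no tumor-purity
claim.

## Co-expression networks

Importance weights: one seeded, single-threaded random-forest
regression per target gene (`mtry = ⌊√p⌋`, 500 trees, impurity
importance, per-target normalization to sum 1). Directed weights are
symmetrized by the maximum — the strongest directional evidence defines
the pair — and pairs with Spearman ρ ≤ 0 are discarded: these networks
model positive co-expression. Edge cutting is either top-k (the
source's realized 5600 for 3108 genes) or a binary search on k to hit a
target node count, default half the input genes; node count is
nondecreasing in k, ties resolve to the smaller k. Unordered pairs are
counted after symmetrization.

Louvain runs on a seeded node permutation with community labels
canonicalized by first appearance; betweenness is computed on the
unweighted selected graph (the selection already encodes weight). The
hub rule "betweenness > mean + 2·SD" is a documented surrogate for
unspecified "default cutoffs", parameterized, and reported alongside a
per-community top-5 so both readings are available; note that on very
small graphs the 2·SD rule can flag nothing (a 5-vertex star's center
sits below mean + 2·SD).

## Deconvolution

`estimate_fractions()` is a transparent reference-based surrogate for
SVR-based web deconvolution: non-negative least squares per sample on
the shared gene panel (linear scale — log2 input must be exponentiated,
and the analysis drivers log when they do), renormalization to sum 1,
and a permutation p-value (fraction of gene-shuffled samples whose NNLS
fit correlation reaches the observed one, with the +1 correction that
keeps p in (0, 1]). Identical reference columns are rejected as
non-identifiable. Samples failing the fit filter (p ≥ 0.05) are dropped
before stage comparisons, exactly and only those.

## Prognosis

Eq.-style scoring divides each signature gene by its *variance* (n−1
sample variance across the scoring dataset, or variances frozen from a
training matrix) — exactly as defined, although this makes the score
scale-dependent; an SD-normalizing flag exists for sensitivity
analyses. Median dichotomization sends ties to the low group for
determinism. Survival is administratively truncated at 60 months (the
5-year endpoint) for screening and KM/log-rank; Cox models use Efron
ties. The endpoint semantics (overall vs disease-specific) are treated
generically as (time, event). In the multivariate model stage enters
categorically by default (ordinal via a switch), and each covariate
additionally gets a multi-df likelihood-ratio p so "independent
prognostic value" is a single test, not five level-wise ones.

## Problem sizes

The test suite and acceptance script run the full screen on 20
cohorts of 2000 genes × 180 samples, network recovery on 20–60-gene
panels at 30–200 samples, deconvolution on 200-gene/5-cell-type panels
with 100 permutations, and Cox recovery at n = 500 over 20 replicates —
sizes chosen so each property is measured with comfortable Monte Carlo
margin while the whole suite stays interactive.
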