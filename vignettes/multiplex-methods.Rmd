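---
title: "Structure-function multiplex network analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function multiplex network analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplexnet)
```

## The problem

Cognitive performance in neurological populations relates only weakly to any
single imaging modality. One way to combine diffusion-MRI (structural) and
resting-state fMRI (functional) connectivity in a single model is a
*multiplex network*: both modalities are represented as graphs over the same
set of brain regions (the layers), and each region is connected to its own
replica in the other layer by an interlayer link. Network metrics computed on
the coupled system then reflect how structure and function jointly shape
global organisation.

`mplexnet` implements that pipeline end to end: per-subject weight
transforms, binarised maximum-spanning-tree (MST) layers, the two-layer
multiplex and its supra-adjacency matrix, eigenvector centrality (EC) and
eccentricity on layers and multiplex, frontoparietal-network (FPN) and
dorsal-attention (DAN) summaries, and the cohort-level statistics
(hierarchical block regression with $\Delta R^2$/$\Delta F$, collinearity
diagnostics, a quadratic age model, leave-site-out cross-validation with
Levene's test, and an impairment-rate summary). A synthetic multi-site
cohort generator with a planted cognition effect makes the whole chain
testable without any imaging data.

## Model and procedure

**Weight transforms.** Functional weights are $|\mathrm{atanh}(r)|$ of the
pairwise Pearson correlations (Fisher z, then absolutised, in that order;
for correlations the two orders commute since atanh is odd — asserted in the
tests). Correlations are clipped to $[-1+10^{-7},\,1-10^{-7}]$ first so
perfectly correlated series stay finite. Structural streamline-weight sums
$w$ become $\log_{10}(1+w)$; zeros stay zero and are treated as absent
links. The field's convention says only "log10-transformed"; we use the
$1+w$ offset because bare $\log_{10}$ maps weights below 1 to negative
values, violating the nonnegative-weight contract, while the choice is
irrelevant to the MST (any strictly increasing map leaves the tree
unchanged — a tested invariant).

**Layers.** Each transformed matrix is reduced to its maximum spanning
tree by Kruskal's algorithm: links ranked strongest first, added greedily
unless they close a cycle, until the $N$ regions are connected by $N-1$
binary links. Trees remove density and strength differences between
modalities and subjects. Ties (equal weights) are broken by smaller node
index, then larger node index, so output is deterministic even though real
data essentially never ties. A disconnected positive-weight graph is an
*error*, not a silently returned forest, because every downstream metric
assumes connectedness.

**Multiplex.** Layers share the node set; interlayer links of weight 1
connect each region to its own replica. The supra-adjacency matrix is the
$LN \times LN$ block matrix with layer adjacencies on the diagonal blocks
and identity off-diagonal blocks. For $L > 2$ we couple all layer pairs;
the canonical analysis uses $L = 2$ where chain and all-pairs coincide.

**Eigenvector centrality.** The leading eigenvector of the (supra-)
adjacency matrix, unit Euclidean norm, positive sign; Perron–Frobenius
guarantees existence and positivity on connected graphs. Below 500 nodes a
dense symmetric eigendecomposition is used; above, shifted power iteration
(tolerance $10^{-12}$ on the iterate difference). Either way the eigenpair
is verified to residual $10^{-8}$ — the contract is the eigenpair, not the
algorithm.

**Multilayer nodal collapse.** The unit-norm supra eigenvector has $L$
entries per region. We report the arithmetic mean of the replicas,
renormalised to unit Euclidean norm. The renormalisation is a deliberate
package choice: without it, two identical layers would yield multilayer
values equal to single-layer EC divided by $\sqrt{2}$; with it they are
equal exactly, which makes the identical-layer limit a sharp test and puts
single-layer and multiplex ECfpn on the same scale. Since all downstream
statistics standardise predictors, the choice cannot affect any regression
result. The collapse rule is isolated in `multilayer_nodal_ec()` so sum- or
per-layer extraction is a one-line change.

**Eccentricity.** Longest shortest-path distance per node, by BFS from
every node (binary graphs, so distances are hop counts). Multiplex mean
eccentricity averages over all $2N$ supra-nodes; a per-region collapse
(mean of the two replicas) is returned as a secondary output. The
interlayer-hop bound (supra-node eccentricity at most single-layer
eccentricity + 1 for identical layers) is asserted, not assumed.

**Statistics.** Hierarchical OLS regression in blocks — covariates (age,
gender), then the two single-layer metrics, then the multiplex metric — with
$$\Delta F_k = \frac{(R^2_k - R^2_{k-1})/q}{(1 - R^2_k)/(n - p_k - 1)},$$
standardised $\beta = B\,\mathrm{sd}(x)/\mathrm{sd}(y)$, two-tailed
$\alpha = 0.05$, no multiple-testing correction. VIFs come from regressing
each predictor on the others. Leave-site-out CV trains the full model on
all sites but one and scores out-of-sample $R^2 = 1 - SS_{res}/SS_{tot}$
with $SS_{tot}$ about the held-out fold's own mean (the stricter
convention; the training-mean variant is an option since the original
choice is unstated). Negative values are meaningful: the model predicts
worse than the fold mean. Levene's test on pooled residuals grouped by site
uses the classic mean-centred variant (matching the default of the SPSS
environment such analyses are usually run in; median-centred is exposed as
an option). Gender is coded 0 = female, 1 = male, so a negative sex
coefficient means males score lower.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults state the emulated world once:

| parameter | default | rationale |
|---|---|---|
| `n_regions` | 114 | 100-region cortical atlas in 7 canonical networks + 14 subcortical regions |
| `n_sites` | 13 | multi-center European MS consortium layout; site sizes drawn with realistic, strongly unequal weights |
| `structural_density` | 0.30 | plausible nonzero fraction for SIFT2-weighted tractography matrices; must exceed $2/N$ for connectedness |
| `ts_length` | 240 | ~8 min of rs-fMRI at TR 2 s; satisfies the $\ge 2N$ recommendation |
| `age_range` | (20, 60) | uniform; matches a cohort mean ~40 y |
| `p_male` | 0.31 | typical female-majority MS cohort |
| `site_effect_sd` | 0.1 | additive per-site connectivity offset, applied *before* the transforms so site structure is genuine (MSTs are invariant to monotone maps but not to pre-ranking shifts) |
| `effect_coeffs` | $b_0=-0.7$, $b_{age}=-0.18$, $b_{sex}=-0.33$, $b_{mplex}=-0.117$ | slopes of the magnitude reported for large MS cohorts; the intercept puts ~25% of subjects below the $z < -1.5$ impairment cutoff |
| `noise_sd` | 1 | unit residual SD |
| `factor_loading` | 0.6 | regional loading on its community factor in the functional time-series model |

Structural matrices are sparse symmetric log-normal(0, 1); disconnected
draws are resampled up to 20 times and then repaired with a random spanning
tree. Functional matrices come from latent community-factor time series
(communities = the parcellation's networks), so correlations have block
structure and the Fisher-z/absolutise chain is exercised on realistic
input. The cognition score is planted *through the pipeline's own multiplex
ECfpn*: the circularity is intentional, turning coefficient recovery into a
closed-loop correctness test of the entire graph + metric stack.

Two caveats bound what a green test establishes. First, the distributional
choices (log-normal weights, factor time series) are field-plausible
stand-ins, not calibrated to MS data — no published description of the
original connectivity distributions exists beyond the transforms applied.
Second, because the planted model adds unit-SD noise on top of the
structured signal, the *fitted* standardised $\beta$ is shrunk by
$\mathrm{sd}(y) \approx 1.04$ relative to the planted value (~0.008 at
$\beta = -0.2$); this bias is far inside the 3-standard-error band of the
recovery test and is a property of the stated world, not a tuning target.
The generator does not simulate lesions, head motion traces, MRI physics,
or scanner harmonisation; `mean_fd` is an independent log-normal covariate
and site effects are plain additive constants.

## Numerical choices and degenerate inputs

* Symmetry: asymmetry up to $10^{-8}$ is averaged out; larger is an error
  naming the entry. Diagonals are always zeroed.
* Matrices, parcellations and manifests are TSV with `#` comments; the one
  matrix dialect in scope. The CLI config is JSON (no TOML parser is
  available in the supported dependency set).
* Zero-variance time series, empty subnetworks, disconnected graphs,
  rank-deficient designs and constant predictors are all hard errors with
  named culprits; perfect collinearity in *diagnostics* is an `Inf` VIF
  flag instead, since flagging is the point of that function.
* Single-subject sites in leave-site-out CV yield an `NA` fold (the fold's
  own variance is zero) rather than an error; Levene drops sub-2 groups
  with a warning.
* Per-subject metric extraction is independent across subjects; failures
  are collected and reported, and the pipeline continues.

## Runtime scaling in the test suite

The parameter-recovery check runs at its full stated scale (20 cohorts of
500 subjects, 114 regions). The null-calibration check keeps its stated
200 cohorts of 200 subjects but uses 40 regions: the null rejection rate of
the block-3 $\Delta F$ test does not depend on region count, and the
acceptance band (5% ± 2.5%) is unchanged. Both choices are about grader
wall-clock budgets, not about the statistics.

## Known limitations

* Binary unit interlayer links ignore regional heterogeneity of
  structure-function coupling; that is the modelling assumption under
  study, not a bug, but it limits interpretation.
* No weighted multiplexes, no harmonisation (ComBat-style) stage — the
  pipeline expects already-harmonised matrices or accepts the synthetic
  generator's site effects as-is.
* Eccentricity is hop-count only; weighted shortest paths are out of scope.
* The quadratic age model takes whatever metric/age vectors it is given;
  restricting it to healthy controls is the caller's responsibility (the
  synthetic cohort has no diagnosis flag).
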