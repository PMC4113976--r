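---
title: "Structural covariance networks from regional MTR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from regional MTR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swmnet)
```

## The problem

Regional structural properties of the brain covary across individuals:
when one region's myelin content is high in a subject, anatomically or
functionally related regions tend to be high as well. A *structural
covariance network* makes this precise: nodes are cortical regions,
edges are statistical associations between regional measurements across
subjects. `swmnet` implements this analysis for the superficial white
matter (SWM) — the ~3 mm layer of short association U-fibers under the
cortex — measured by the magnetization transfer ratio (MTR), a
myelin-sensitive MRI contrast expressed in percent signal loss
(`MTR = 100 * (M0 - MS) / M0`; voxels with MTR ≤ 10% are treated as
noise and excluded from regional means).

The node space is fixed: 39 Brodmann-style areas per hemisphere
(`default_atlas()`), each assigned to one of five lobes (frontal 9,
parietal 6, paralimbic 14, temporal 6, occipital 4 areas per
hemisphere), with a perfect homotopic matching between hemispheres.
Composite areas (1+2+3, 24+33, 29+30) and the cuneus are atomic nodes.
Left-hemisphere nodes come first, so the homotopic partner of node
*i* ≤ 39 is node *i* + 39; this ordering is a package convention — every
statistic computed here is invariant to the within-lobe order.

## Network estimation in the n ≪ k regime

The scientific crux is estimating a Gaussian graphical model on k = 78
variables from n ≈ 15 subjects per group. Classical partial-correlation
estimators need n > k; instead, the covariance is estimated by analytic
shrinkage toward a heteroscedastic diagonal target (the covariance of a
graph of isolated nodes): correlations are shrunk toward zero with
intensity

λ = Σ_{i≠j} Var̂(r_ij) / Σ_{i≠j} r_ij²,

clipped to [0, 1], while empirical variances are kept
(`shrink_covariance()`). The result is positive definite for any λ > 0,
so partial correlations can be read off the inverse: with Ω = Σ⁻¹,

p_ij = −ω_ij / √(ω_ii ω_jj)    (`partial_correlations()`).

Two conventions matter. First, the sign: we report p_ij so that a
positive value means positive partial association (edge tallies split
positive/negative). Second, only the correlations are shrunk by
default; variance shrinkage is available behind
`shrink_variances = TRUE` but off, because the diagonal target is meant
to preserve the empirical variances. Linear effects of age and gender
are removed by *variable augmentation*: the two covariates join the ROI
matrix (k = 80), the whole pipeline runs, and only the 78×78 ROI block
is retained (`adjust_covariates()`). This is preferable to
pre-residualization because the covariates are then conditioned on in
the same estimator whose output is interpreted.

Under exact independence of all variables the analytic λ is ≈ 1 (the
numerator equals the denominator in expectation) — the estimator then
correctly returns the diagonal target. λ → 0 only when real correlation
structure dominates the sampling noise. At n = 15, k = 78, λ is
typically 0.7–0.95, i.e. estimated partial correlations are strongly
attenuated; everything downstream must be read on that attenuated
scale.

## Edge inference: the lfdr mixture

Which of the 3003 p_ij are real? The marginal distribution of the
statistics is modeled as a two-component mixture
f = η₀·f₀ + (1−η₀)·f_a, where f₀ is the null and f_a the unspecified
alternative. The local false discovery rate of an edge is the posterior
probability of being null, lfdr(p) = η₀·f₀(p)/f(p), capped at 1. Edges
with lfdr < 0.2 are called *highly significant*; lfdr < 0.5 marks the
Bayesian boundary between null and alternative and delimits the density
band used for topology (below).

Fitting choices (`fit_mixture()`):

* **Null family.** For partial correlations, f₀ is the Hotelling form
  f₀(p; κ) ∝ (1−p²)^((κ−3)/2). κ is *fitted*, not set to n−1: shrinkage
  contracts the null spread, so the effective degrees of freedom are
  much larger than the sample size suggests. For z-scores
  (group/hemisphere contrasts) f₀ is a centered Gaussian with fitted
  scale.
* **Null scale.** Truncated maximum likelihood on the central 75% of
  |values| (the window is a tunable, `window = 0.75`); the central
  region is null-dominated, so contamination bias is small.
* **Null proportion.** Central matching:
  η₀ = (fraction of |values| inside the window) / P₀(inside window).
* **Marginal density.** A Grenander (non-increasing) density estimated
  on the null p-value scale u = P₀(|X| > |x|): under the null u is
  uniform, and lfdr = η₀ / g(u). This construction pools evidence over
  tail prefixes (the slope of the least concave majorant of the ECDF),
  is automatically monotone in |statistic| — a larger statistic never
  has a larger lfdr — and stays defined where f₀ underflows.

Group differences use the Fisher transformation:
z = (atanh p_A − atanh p_B) / √(1/(n_A−3) + 1/(n_B−3)), followed by the
Gaussian-null mixture on the 3003 z-scores; a Jarque–Bera p-value on
the z sample is reported as the normality audit. The hemisphere
contrast compares each left-intrahemispheric edge with its homotopic
right counterpart through the same signed construction with
SE = √(2/(n−3)). The signed difference is used deliberately: folding
the magnitudes first makes the null z cusped and leptokurtic, which the
Gaussian null cannot calibrate and which a Jarque–Bera check rejects.
Direction labels (`LH>RH`, `AD<control`, ...) are assigned by
partial-correlation magnitude, independently of sign, because the
difference tables are defined that way. The two hemisphere samples come
from the same subjects; the independent-samples SE is a documented
approximation (the dependence is noted, not modeled). The hemisphere
contrast runs per group.

## Laterality of the MTR maps

Separately from the networks, regional myelination asymmetry is scored
per subject and homotopic pair as (L − R)/(L + R), positive = leftward.
Inference is a permutation GLM with age and gender as nuisance
covariates (`laterality_glm()`): the between-group contrast permutes
group labels after residualizing on the nuisance design and
re-residualizes each permuted draw (Freedman–Lane); the within-group
one-sample contrast uses random sign flips of the covariate-adjusted
scores (adjusted is the default; raw scores via `adjust = FALSE`).
Two-sided p-values use the (1 + exceedances)/(1 + n_perm) estimator —
never exactly zero — and are corrected across the 39 pairs by
Benjamini–Hochberg step-up; FDR-corrected p < 0.05 is called
significant. With the default 10,000 permutations the smallest
achievable q is 39/10001 ≈ 0.004; at n_perm below ~800 the q < 0.05
threshold is unreachable for a single signal, which matters when
reducing permutations for speed.

## Macro-network: integration and segregation by lobe

The 78 nodes collapse onto 10 lobe-hemisphere clusters. Within-region
association is summarized by Gaussian entropy H = −½·ln det(P_N) on the
partial-correlation submatrix (0 iff the submatrix is the identity);
between-region association by mutual information
MI = ½·ln(det P_N1 · det P_N2 / det P_N1∪N2) ≥ 0. Note the identity
with this H convention is MI = H(N1∪N2) − H(N1) − H(N2). Both are in
nats. Entropies are computed on the partial-correlation submatrix by
design (a correlation-matrix mode exists behind
`use_correlations = TRUE`). H and MI values are ranked weak/medium/
strong by one-dimensional k-means (k = 3, 50 restarts, clusters ordered
by centroid); when two groups are summarized together the ranking is
fitted on the pooled values — separately for H and for MI — so levels
are comparable across groups. A region or region pair is flagged
significant when it contains at least one called edge (lfdr < 0.2);
this proxy is configurable via the `called` argument. Fewer than three
distinct values (an exactly null model) degrade to all-"weak" with a
warning.

## Binary topology and density integration

Networks are binarized either at an lfdr threshold or to an exact edge
density (the `round(density·3003)` smallest-lfdr edges; ties broken by
larger |p_ij|, then node order). Metrics on the 0/1 adjacency:

* degree k_i = Σ_j a_ij; *hubs* are nodes whose density-integrated
  degree is at least the 75th percentile (linear-interpolation
  percentile) of the integrated-degree distribution — with 78 distinct
  degrees that is 20 nodes; an all-equal degree vector saturates the
  rule and is flagged degenerate. Hubs are computed from the pooled
  two-hemisphere distribution (per-hemisphere tables are display only).
* global efficiency: mean over pairs of 1/d_ij with 1/∞ = 0
  (disconnected pairs contribute zero — the networks here have isolated
  nodes, so this convention is load-bearing); local efficiency: mean
  over nodes of the efficiency of the subgraph induced by each node's
  neighbors, zero for nodes with < 2 neighbors. Both are computed by
  breadth-first search in compiled code and are checked against a
  Floyd–Warshall oracle on exhaustive small graphs in the test suite.
* modularity Q = Σ_c (e_cc − a_c²) for a given partition;
  `best_partition()` maximizes Q by the deterministic greedy
  agglomerative search (igraph's fast-greedy implementation).

Because a single threshold confounds topology with edge count, metrics
are *density-integrated*: the lfdr band (0.2, 0.5) maps to an edge
density interval — the fractions of pairs with lfdr below each
endpoint — and each metric is averaged over `n_points = 30` evenly
spaced densities in that interval (densities treated as equally
likely). If the band collapses (e.g. no edge reaches lfdr < 0.5) a
warning is issued and the single density is used; an entirely empty
network yields zero for all metrics. Group contrasts of integrated GE,
LE and Q use a label permutation test that re-runs the *entire*
pipeline (shrinkage → mixture → binarization → metric → integration)
per shuffle, with the +1-corrected two-sided p. A density-matched
comparison (`compare_density_matched()`) evaluates both groups on a
common density grid instead; its per-density flags need a
multiple-comparison correction downstream.

## The synthetic-cohort generator

No MTR cohort is distributed with the package, so every stage is
exercised against sparse Gaussian graphical models built by
`build_precision()`:

* edges are placed uniformly at random under a per-node degree cap
  (⌊(1−min_eig)/|ρ|_min⌋), magnitudes drawn uniformly from the
  requested range with signs positive with probability 0.9 (structural
  covariance is predominantly positive);
* positive definiteness is enforced by *selective damping*: while the
  smallest eigenvalue of the unit-diagonal precision is below
  `min_eig = 0.1`, the edges most involved in the offending eigenvector
  are shrunk by 7%, never below the range minimum. Because positive
  definiteness of a graphical model depends only on its implied
  partial-correlation matrix, a uniform diagonal shift cannot preserve
  the magnitudes; selective damping keeps the drawn distribution as far
  as the geometry allows. A consequence worth knowing: ~100
  mostly-positive edges on 78 nodes cap the feasible mean magnitude
  near 0.35 regardless of construction.

Cohorts are multivariate-normal draws around per-area regional means
(default uniform 30–60 MTR%, mirrored across hemispheres; marginal SD
2 MTR%), with optional linear age/gender effects, ages uniform on
55–80 years, gender Bernoulli(0.5) coded 0/1, and hemispheric
asymmetry offsets added to the left member of homotopic pairs (an
offset δ on a pair with baseline mean μ implies a population laterality
score δ/(2μ+δ)). `two_group_scenario()` derives a second population by
zeroing "lost" edges and planting "gained" ones, refusing modifications
that break positive definiteness. Everything is reproducible from a
single integer seed.

What the generator does *not* emulate: voxel-level images, scanner
noise fields, partial-volume effects, segmentation error, non-Gaussian
marginals, or site/batch structure. Passing tests therefore demonstrate
the statistical machinery under its own assumptions — multivariate
normality with a sparse precision — not robustness to the artifacts of
real MRI data.

## What the simulations can and cannot show

The edge-calling rule lfdr < 0.2 is designed for high positive
predictive value. At the study's own scale, however, the detectable
regime is narrow. With n = 15 and 100 planted edges whose feasible mean
magnitude is ≈ 0.35 (see above), planted effects sit 1.1–1.9 null-SDs
out on the Fisher-z scale, while an edge needs ≈ 4 SDs to clear
lfdr < 0.2; the calibrated estimator therefore calls few or no edges,
and `ppv_simulation()` reports an undefined (NA) PPV for replicates
without calls, with 0 returned when nothing is ever called. This is
the honest behavior of a conservative rule under weak separation, not
an implementation artifact: tests show the same machinery attains
high-precision calls when separation is adequate (e.g. 50 edges at
magnitudes 0.4–0.7 with n = 30, or differential edges at n = 500 per
group). Similarly, a 1.5-SD laterality shift at n = 15/group has
theoretical power ≈ 0.6 once the 39-way FDR correction is paid
(noncentral t, ncp ≈ 4.1, critical p ≈ 0.05/39), so detection rates
near 60% are expected, not a defect.

## Numerical and runtime choices

* Permutation defaults are 10,000 (laterality) as in the protocol; the
  topology permutation test re-runs the full estimation pipeline per
  shuffle, so `run_pipeline()` leaves it opt-in
  (`topology_n_perm = 0`); enable it explicitly for real analyses.
* Test-suite and validation problem sizes (replicate counts, n_perm of
  150–1500, 4–10 density grid points) are chosen so the whole suite
  runs in about a minute on one CPU while keeping Monte-Carlo error
  well inside the asserted margins; the vignette states them as package
  choices.
* p-values from permutations use the +1 correction; mixture p-values
  are floored at 1e-15 before the Grenander step; determinants go
  through `determinant(log = TRUE)`; positive definiteness is checked
  by Cholesky/eigenvalues, not determinants.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; `run_pipeline()` derives per-stage seeds from
  the master seed, so reports are byte-identical across reruns.

## Known limitations

* The hemisphere contrast treats the two dependent samples as
  independent in the SE; lfdr calibration absorbs most of the
  mismatch, but the z-scores are not exactly standard normal.
* η₀ estimation by central matching saturates at 1 when alternatives
  overlap the null bulk; in that regime lfdr inference is conservative.
* The greedy modularity search is deterministic but not exhaustive; on
  small graphs it can sit up to ~0.15 below the exhaustive maximum Q.
* Edge classes, tallies and hub tables assume the fixed 78-node atlas;
  other atlases must satisfy the same invariants (balanced hemispheres,
  homotopic matching) to use the hemisphere machinery.
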