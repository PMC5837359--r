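---
title: "Methods: tau burden and the functional connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tau burden and the functional connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Tauopathies differ in where pathological tau accumulates and in what it does
to large-scale brain function. Under a trans-neuronal-spread model, tau
propagates along synaptic connections, so strongly connected regions (hubs of
the functional connectome) should accrue more tau; under metabolic or trophic
models other graph properties should predict accumulation. This package
implements an analysis pipeline that relates regional tau-PET binding
potential (BP~ND~, reference-region normalized and therefore zero in the
cerebellum) to nodal graph properties of the resting-state functional
connectome, in two disease groups with dissociated tau topographies — an
Alzheimer-type pattern with distributed, connectivity-coupled cortical tau,
and a PSP-type pattern with tau confined to subcortical and brainstem
structures — plus controls.

Because the motivating cohort data are not publicly deposited, the package
includes a first-class synthetic-cohort generator with *planted, recoverable
effect sizes*. Every downstream statistic can therefore be validated against
known ground truth.

## Pipeline overview

1. **Association matrices** (`compute_association_matrix`): all pairwise
   Pearson correlations between node time series, Fisher-z transformed
   (`atanh`), correlations clipped to |r| ≤ 1 − 10⁻¹² so collinear pairs map
   to a large finite value. Group averages are element-wise means of z.
2. **Proportional thresholding** (`threshold_graph`): the maximum-weight
   spanning tree of the z matrix is retained unconditionally (built by
   Kruskal on descending z; equivalently the minimum spanning tree of
   max(z) − z), then edges are added in descending z order until
   `max(N−1, round(d·N(N−1)/2))` edges are present. This guarantees a single
   connected component at every density d ∈ 1–10%; the primary analysis
   density is 6%.
3. **Nodal metrics** (`metric_panel` and friends): weighted degree and
   participation coefficient are analysed in raw, weighted form; clustering,
   betweenness, closeness, local efficiency and eigenvector centrality are
   computed on the binarized graph and divided by their mean over an ensemble
   of degree-preserving random graphs, dissociating them from the degree
   sequence.
4. **Tau-network statistics** (`run_cohort_analysis`): node-wise correlations
   of group-mean metric against group-mean BP~ND~; per-subject tau burden
   (whole-brain mean for AD and controls, subcortical mean for PSP) regressed
   against whole-brain metric averages within group; an AD-vs-PSP moderation
   (interaction) model; per-node gradient maps (slope of nodal metric on
   burden within group) with sign tests and gradient-vs-tau correlations; and
   Jennrich tests comparing group-averaged association matrices.

## Statistical components

**Jennrich test.** For correlation matrices R₁, R₂ estimated from n₁, n₂
observations, with pooled matrix R̄ = (n₁R₁ + n₂R₂)/(n₁+n₂),
Z = √(n₁n₂/(n₁+n₂)) · R̄⁻¹(R₁ − R₂) and
χ² = ½·tr(Z²) − dg(Z)ᵀ S⁻¹ dg(Z), where S = I + R̄ ∘ R̄⁻¹ (elementwise), on
p(p−1)/2 degrees of freedom. Identical inputs give χ² = 0 exactly; type-I
calibration is verified by simulation. With many more nodes than subjects the
pooled matrix is singular; the implementation offers a diagonal ridge
(flagged in the result) and node-subset evaluation. The pipeline default is a
subset of 30 evenly spaced non-cerebellar nodes with no ridge; both knobs are
exposed because no exact reconstruction of a full-parcellation Jennrich test
at n ≈ 17 is possible.

**Moderation.** `metric ~ burden + group + burden:group` by OLS with a 0/1
group indicator. Δr² = r²(full) − r²(no interaction) equals the squared
semipartial correlation of the interaction term (verified to 10⁻¹⁰), and
F = Δr²(n−4)/(1−r²_full) on (1, n−4) df, so two groups of 17 give the
characteristic F(1, 30). Δr² and F are invariant to which group is coded 1.
Burden can be residualized on age (OLS with intercept, pooled across the two
groups entering the model) before fitting; the pooling choice is ours, since
partialling schemes differ across packages.

**Sign test.** For n nonzero nodal gradients with k positive,
Z = (2k − n)/√n, and the p-value is the exact two-sided binomial probability
(doubled smaller tail, capped at 1 — identical to `binom.test` at p = ½).
Zero gradients are excluded and counted. Two-sided p-values are used
throughout the package.

**Network assignment.** A node belongs to an intrinsic connectivity network
if any voxel of that network's spatial map at Z ≥ 2.6 lies within 5 mm
(inclusive) of the node centroid, with voxel coordinates mapped through a
4×4 affine. Multiple memberships are allowed.

## The synthetic-cohort generator

`generate_cohort` builds one base network per cohort and, per subject, a
latent disease severity b ~ U(0, 0.1) for controls and U(0.1, 1) for the
disease groups, a tau map, a burden-modulated network, and an i.i.d. Gaussian
time series whose covariance is Σ = load·W/max(rowSums(W)) + I. Diagonal
dominance (load < 1) guarantees positive definiteness; every covariance in
the test suite passes a Cholesky factorization. BOLD realism (temporal
autocorrelation, hemodynamics) is deliberately not attempted: every
downstream statistic consumes only the correlation matrix, so i.i.d. samples
suffice and keep the generator analytically transparent.

Tau regimes:

* AD mode: τᵢ = β₀ + β₁·b·sᵢ/mean(s) + ε, coupling tau to baseline nodal
  strength (the trans-neuronal-spread signature), with s averaged over
  non-cerebellar nodes.
* PSP mode: τᵢ = β₀ + β₁·b·1[subcortical] + ε.
* Controls: τᵢ = β₀ + ε.

Cerebellar nodes are forced to 0 (PET reference region) and values are
floored at 0; real BP~ND~ can be slightly negative, but the synthetic truth
keeps it non-negative for simplicity.

Edge modulation: AD weakens every edge by the mean tau of its endpoints,
wᵢⱼ ← wᵢⱼ(1 − γ·b·(τᵢ+τⱼ)/2); PSP strengthens cortico-cortical edges by
(1 + γ·b) and weakens any subcortical-touching edge by (1 − γ·b); controls
are unmodulated. The precondition γ·b·max(τ) < 1 keeps weights positive.

### Why the defaults look the way they do

The covariance contract divides the weight matrix by its own maximum row sum.
A consequence worth stating plainly: **any modulation that is close to a
uniform rescaling of W cancels out of the correlation matrix.** Planted
disease effects are therefore only recoverable if (i) the modulation is
differential across edges and (ii) the maximum-strength row is itself stable
under modulation. The generator achieves (ii) anatomically: within-cerebellum
edges are boosted (`cerebellar_boost = 4`), mirroring the strong
intra-cerebellar coherence of resting-state recordings, so the normalization
row belongs to the tau-free reference region and AD weakening passes through
to the measured correlations instead of cancelling.

Default scale and parameters (all exposed in `cohort_config`): 130 nodes
(100 cortical in 4 communities, 20 subcortical, 10 cerebellar — the deep
nodes share one community), T = 250 samples, groups 17/17/12; p_in = 0.25,
p_out = 0.02 (≈ 8 planted partners per node, roughly filling the 6% edge
budget); hub_fraction = 0.1 with hub_boost = 1.2; β₀ = 0.5, β₁ = 0.8,
σ = 0.05, γ = 0.4, load = 0.98. The BP~ND~ scale (β₀, β₁) is arbitrary —
the real dynamic range per group is not recoverable from published figures —
and the remaining values were chosen once, during design, so that planted
effects sit above the sampling-noise floor of T = 250 correlation estimates
while respecting γ·max(τ) < 1. 598-node generation is supported but not the
default.

### What passing tests do and do not show

The generator shares with real resting-state data the features the analysis
consumes — community and hub structure, a stable reference region,
group-dependent tau topography, burden-dependent edge modulation — and omits
temporal autocorrelation, measurement artefacts, head motion, spatial
smoothness and atlas geometry. Signature-recovery tests therefore demonstrate
that the *pipeline* detects effects of the planted form at realistic sample
sizes; they say nothing about effect sizes in real cohorts. Two sub-checks of
the recovery suite operate at their power boundary by construction: the
AD gradient-vs-tau correlation (a second-order effect whose per-node gradient
noise is large relative to its true value of about −0.1) and the PSP
burden-strength slope (at high burden, grown cortical hub rows can overtake
the cerebellar reference row in lucky realizations, flattening the slope).
Their seed-level recovery rates hover near, and sometimes below, the 90%
bar; we report this rather than retuning the generator to the test.

## Numerical choices

* Edges are ranked by **signed** z (strongest positive correlations enter
  first); negative correlations are never retained except as forced backbone
  edges. Ranking by |z| is available (`rank_by = "absolute"`).
* Ties in z are broken by lexicographic node-pair order, making thresholding
  and the Kruskal backbone fully deterministic.
* The edge budget uses round-half-away-from-zero (base R's `round` banker's
  rounding would make some budgets depend on parity).
* Betweenness is normalized by (N−1)(N−2)/2; closeness is (N−1)/Σd.
* Local efficiency of a node is the global efficiency of the subgraph
  induced by its neighbours; disconnected neighbour pairs contribute 0;
  degree < 2 gives 0.
* Eigenvector centrality is computed by power iteration on A + I (same
  eigenvectors as A; the shift guarantees convergence on bipartite graphs),
  returned with non-negative entries and unit L2 norm; non-convergence after
  `max_iter` raises an error reporting the residual.
* Null-model rewiring performs `swap_factor · E` attempted double-edge
  swaps, rejecting any swap creating self-loops, multi-edges or a
  disconnected graph (connectivity is rechecked by BFS after every accepted
  swap and the swap reverted if it fails). This keeps closeness and
  efficiency well-defined on every ensemble member. The ensemble size
  defaults to 1000 in configuration and 100 in tests.
* Normalization divides the observed metric by the ensemble mean (the
  standard small-world convention); nodes with a zero ensemble mean get 0 and
  are flagged.
* Louvain runs per subject on retained z weights (negative retained backbone
  weights clipped to 0 for the community search), seeded and logged;
  group-average graphs can be used instead by calling `louvain_partition` on
  the averaged matrix.

## Problem sizes in the test suite

Unit and acceptance tests run at desk scale, chosen as the package's own
test conditions: oracle equivalence on 200 random graphs of up to 12 nodes
against brute-force implementations (Floyd–Warshall distances, explicit
geodesic counting, dense eigendecomposition); the thresholding contract on
100 random 60-node matrices at all ten densities; null-model self-consistency
on 100-node random graphs with 100-member ensembles; Jennrich and moderation
calibration with 500 replicates each; signature recovery on 20 full-scale
synthetic cohorts (130 nodes, T = 250, 46 subjects) using raw weighted
degree. The analysis drivers under `analysis/` run the same code at full
configuration, including null-normalized binary metrics.

## Known limitations

* The Jennrich test cannot be computed on a full parcellation with n ≈ 17
  subjects per group (singular pooled matrix); node subsets or a ridge are
  approximations, and no numerical equivalence to a full-scale computation is
  claimed.
* The generator's correlation ceiling is set by the max-row normalization:
  per-edge correlations scale like load/partners, so very dense or very
  heterogeneous base networks push planted effects under the T = 250
  sampling-noise floor. This is a property of the simulation contract, not of
  the analysis code.
* Gradient maps use per-subject, per-node metric values and inherit their
  full sampling noise; with 17 subjects per group, gradient-level inferences
  are low-powered, which the sign test (aggregating over nodes) partly
  mitigates.
* No multiple-testing correction is applied by default (raw p-values are
  reported per metric and density, matching standard practice for this
  analysis family); a Benjamini–Hochberg adjustment can be applied to the
  tidy results table by the user.
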