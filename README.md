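# tauconnect

Links regional tau pathology, measured as tau-PET non-displaceable binding
potential (BP<sub>ND</sub>) per brain region, to graph properties of the
resting-state functional connectome across disease groups. The package is
aimed at neuroimaging researchers testing network-based hypotheses about tau
accumulation — trans-neuronal spread (tau follows strong connections),
metabolic vulnerability (tau follows connector hubs), or trophic failure
(tau follows weak clustering) — in cohorts with dissociated tauopathies such
as Alzheimer's disease (distributed cortical tau) and progressive
supranuclear palsy (subcortically restricted tau), plus controls.

## What it computes

**Connectome construction.** Per-subject association matrices
z = atanh(r) from node×time series; proportional thresholding at densities
d ∈ 1–10% that always retains the maximum-weight spanning tree, so every
graph holds exactly max(N−1, round(d·N(N−1)/2)) edges and is connected.

**Nodal graph metrics.** Weighted degree k<sub>i</sub> = Σ<sub>j</sub>
w<sub>ij</sub> and participation coefficient
P<sub>i</sub> = 1 − Σ<sub>s</sub>(κ<sub>is</sub>/k<sub>i</sub>)² (Louvain
communities) in raw weighted form; clustering, betweenness, closeness, local
efficiency and eigenvector centrality binarized and normalized against
degree-preserving, connectivity-preserving random graphs (double-edge swaps,
compiled in C++).

**Tau-network statistics.**

- node-wise Pearson/Spearman correlation of group-mean metric vs group-mean
  BP<sub>ND</sub> over non-cerebellar nodes;
- per-subject tau burden (whole-brain or subcortical mean BP<sub>ND</sub>,
  optionally age-residualized) regressed on whole-brain metric averages
  within group;
- moderation analysis between two groups: metric ~ burden + group +
  burden×group, Δr² = r²(full) − r²(reduced),
  F = Δr²(n−4)/(1−r²<sub>full</sub>) on (1, n−4) df;
- per-node gradient maps (OLS slope of nodal metric on burden), sign tests
  Z = (2k−n)/√n with exact binomial p, and gradient-vs-tau correlations;
- the Jennrich χ² test for equality of two correlation matrices,
  χ² = ½tr(Z²) − dg(Z)ᵀS⁻¹dg(Z) with
  Z = √(n₁n₂/(n₁+n₂))·R̄⁻¹(R₁−R₂), S = I + R̄∘R̄⁻¹.

**Synthetic cohorts.** Because the motivating cohort is not deposited, a
generator plants all of the above effects with known truth: a
stochastic-block base network with cortical hubs and a strongly coherent
cerebellar reference block, group-dependent tau maps (strength-coupled in AD
mode, subcortical in PSP mode), burden-dependent edge modulation (weakening
in AD, cortico-cortical strengthening in PSP), and Gaussian time series with
covariance load·W/max(rowSums(W)) + I. Defaults: 130 nodes, T = 250,
groups 17/17/12.

## Worked example

The analysis is organised as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate.R --seed 1      # write synthetic cohort
Rscript analysis/02_connectome.R             # association matrices + graphs
Rscript analysis/03_graph_metrics.R          # metric panel + null model
Rscript analysis/04_tau_stats.R              # the statistical battery
```

Stage 4 prints (seed 1):

```
AD node-wise tau vs weighted degree: r = 0.43 (p = 7.4e-07), rho = 0.41
AD   burden vs mean weighted degree: r = -0.51 (p = 0.037)
PSP  burden vs mean weighted degree: r = +0.47 (p = 0.058)
CTRL burden vs mean weighted degree: r = -0.02 (p = 0.95)
Moderation (AD vs PSP, weighted degree): dr2 = 0.15, F(1,30) = 8.8, p = 0.006
AD gradient-tau correlation: r = -0.12
```

Read: in the AD-mode group, strongly connected nodes carry more tau
(positive node-wise r — the trans-neuronal-spread signature), while rising
tau burden weakens overall connection strength; in the PSP-mode group burden
*strengthens* cortico-cortical connectivity; the moderation F confirms the
slopes differ between the groups, with the F(1,30) structure that two groups
of 17 produce; the negative gradient-tau correlation says weighted degree
falls fastest at high-tau nodes. Controls show no burden relationship. The
same quantities are available programmatically:

```r
library(tauconnect)
bundle <- generate_cohort(cohort_config(seed = 1))
res <- run_cohort_analysis(bundle, density = 0.06)
head(res$results)   # tidy table: analysis, group, metric, density, statistic, value, p
```

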