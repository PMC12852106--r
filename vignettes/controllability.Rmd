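---
title: "Structural controllability of gene regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural controllability of gene regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnctrl)
```

This vignette documents the models implemented in `grnctrl`, the
parameters that matter, the numerical choices made where a definition was
genuinely open, and what the synthetic-data machinery can and cannot tell
you about real data.

## The controllability model

A directed network is *structurally controllable* from a set of driver
nodes if, for generic edge weights, external inputs at those nodes can
steer the full state vector. The minimum driver count follows from the
maximum-matching criterion: split every node `v` into an out-copy `v+`
and an in-copy `v-`, turn each edge `u -> v` into the bipartite edge
`(u+, v-)`, and find a maximum matching `M*` (no two edges sharing a
source or a target). Unmatched in-copies are exactly the nodes that need
an input, so

$$N_D = \max(N - |M^*|,\; 1), \qquad n_D = N_D / N.$$

The floor of 1 covers perfectly matched networks (e.g. a directed cycle):
even a self-sustaining network needs one input to be steered between
states. No published per-network table row reaches a perfect matching, so
the floor never binds on real cohorts; it is pinned by the 3-cycle unit
test. When the floor binds, the reported driver set is the
lexicographically smallest node, so results are reproducible even though
the choice is formally arbitrary.

`N_D` and `n_D` are invariant to which maximum matching is found; the
matching itself is not unique, and `max_matching()` returns whichever
maximum matching its deterministic augmenting-path order produces.

### Edge classes

Every edge is labelled by its role:

* **critical** — removal increases `N_D`. Under the floor rule this is
  slightly narrower than "lies in every maximum matching": in a perfectly
  matched cycle every edge lies in the unique maximum matching, yet
  removing one leaves `N_D = 1`, so cycle edges are *ordinary*.
* **redundant** — the edge belongs to *no* maximum matching. This is the
  operationalisation we adopt for "removable without affecting the driver
  configuration"; the looser phrase is ill-posed when driver sets are
  non-unique. The test is exact: delete the edge's endpoint copies `u+`
  and `v-`; the edge lies in no maximum matching iff the remainder's
  maximum matching plus one is strictly below `|M*|`.
* **ordinary** — neither.

The fractions `l_c + l_r + l_o = 1` by construction. Classification is
implemented incrementally in C++ (one or two single augmenting-path
searches per edge against a frozen `M*`, `O(L·E)` worst case) with a naive
full-recomputation variant (`method = "recompute"`) kept as a
cross-check; the test suite verifies both against exhaustive enumeration
of all matchings on hundreds of small random graphs. That enumeration
oracle caught a genuine subtlety worth recording: when a matched edge
`(u, v)` is deleted, a replacement augmenting path may terminate at the
freed in-copy `v-` without ever touching `u+`, so the incremental test
must search from both freed copies.

## Topology metrics

**Density.** Two conventions circulate for directed networks: the formula
density `L/(N(N-1))` (fraction of realizable edges) and the average
degree `L/N`. Published per-network GRN tables commonly print the latter
under the name "density", and the two differ by the factor `N-1`, which
varies across a cohort — mixing them silently changes correlation
analyses. `grnctrl` therefore always computes both
(`network_density()`), puts the average degree in the `D` column of
cohort tables for comparability with printed tables, and appends
`density_formula` as its own column. The packaged 40-network reference
table pins the convention: its printed `D` column equals `L/N` on all 40
rows to printed precision, while the cohort *correlations* between
density and `n_D` are reproduced by the formula density — the package's
correlation helpers therefore use `density_formula` (with the printed
column available alongside), and `analyze_table1()` demonstrates the
agreement (r = −0.784, partial r = −0.871 to three decimals).

**Heterogeneity.** `H` is the expected absolute degree difference between
two random nodes, normalised by the mean degree:
$$H = \frac{\sum_i \sum_j |k_i - k_j|\, P(k_i) P(k_j)}{\langle k \rangle}.$$
`H = 0` for regular graphs; larger values mean hubs coexist with sparsely
connected nodes. The double sum over distinct degree values equals the
pairwise mean over nodes, which the tests assert.

**Degree exponent.** The scale-free exponent is estimated from the
complementary cumulative distribution `F(k) = P(degree >= k)`: one point
per *distinct* observed degree `k >= 1` (this removes the flat CCDF runs
repeated degrees would create, and makes the fit invariant to duplicating
observations), both axes log10-transformed, ordinary least squares, and
`gamma = 1 - slope`. Zero degrees are dropped before fitting; the
renormalisation this implies only shifts the intercept, never the slope.
At least three distinct positive degrees are required; a regular network
has no meaningful exponent and raises an error. Maximum-likelihood
(Clauset-style) fitting is deliberately out of scope — the CCDF
regression is the estimator this analysis standardises on. Fits outside
`(1.5, 3.5)` are flagged as atypical: values between 2 and 3 are the
scale-free hallmark, and values far outside usually indicate the network
is too small for the fit.

**Which degree?** For `H` and `gamma` the degree flavour (total, in, out)
is configurable; `total` is the default since cohort tables rarely state
the choice. The recovery tests fit out-degrees, where the generator
plants the exponent.

## Robustness to edge failure

`edge_removal_curve()` simulates random edge failure: each of `n_perm`
(default 20) independent permutations of the edge set is removed edge by
edge, recording the fraction of nodes in the largest *weakly* connected
component (GCC fraction — directions ignored for connectivity) after
every removal. The grid is one point per removed edge, `0, 1/L, ..., 1`,
the finest resolution available, on which the trapezoidal AUC is exact
for the recorded step data. Curves start at the intact GCC fraction and
end at `1/N`. Internally each trajectory is computed in reverse with a
union-find structure (adding edges back), which is near-linear in `L`
and guarantees per-run monotonicity.

The AUC is computed on the pointwise mean curve; by linearity of the
trapezoid rule this equals the mean of per-run AUCs to machine precision
(asserted in tests), so the choice is cosmetic. One master seed spawns
per-permutation child seeds, making the whole object a pure function of
`(network, n_perm, seed)`. Whether robustness AUCs should be normalised
by the intact GCC fraction is not standardised; `grnctrl` reports the
unnormalised AUC and exposes the curve so either convention can be
derived.

## TF categorisation

Three axes of TF importance are flagged per network: **Critical** (source
of at least one critical edge), **HO** (outdegree strictly greater than
50), and **HE** (normalised expression strictly above the 3rd quartile).
Expression is normalised by total-count scaling and `log1p`
(`value = log(1 + scale * count / sample_total)`); the scale factor
(default 1e6, CPM-style) cannot affect HE membership because the
transform is strictly monotone within a sample — asserted in tests, so
the unstated constant is immaterial. The HE quantile is computed over the
TFs of the given network's sample; a per-cohort scope would also be
defensible and the quantile and threshold are both arguments.

Across a cohort the categories integrate by *union*: a TF belongs to a
category if it qualified in any network. The three unioned sets are
partitioned into the 7 disjoint Venn regions; because published overlap
counts are sometimes quoted ambiguously (exclusive region vs full
intersection), `integrate_categories()` exposes the member lists so
either reading can be extracted. Pathway enrichment against web services
is out of scope; `write_venn_gene_lists()` exports each region as a plain
gene list for manual submission.

## Cohort statistics

The driver fractions of real cohorts are non-normal (the Shapiro–Wilk
gate in `normality_check()` rejects on the packaged table), so the
phase comparison is rank-based: Kruskal–Wallis with the standard tie
correction, followed by Dunn's post hoc z-tests with two-sided p-values
and Bonferroni correction over all pairs. Pearson and first-order partial
correlations use the textbook formulas with t-transforms (df `n-2` and
`n-3`). All four are implemented from their formulas — not delegated —
so that the test suite can cross-check them against independent
implementations (`stats::kruskal.test`, `stats::cor.test`, and values
computed externally for Dunn) at 1e-8 without the check collapsing into
a tautology. Ties are always corrected for; on the packaged table's
distinct floats the correction is a no-op, but synthetic data may tie.

## The synthetic generator

`generate_network()` emulates the *shape* of GRNs inferred from
single-cell data, not any particular dataset. Design, and what it
emulates:

* **TF-only sources** — candidate regulators are a TF subset
  (`tf_fraction`, default 0.3), as in inference pipelines that restrict
  regulators to a TF list.
* **Two regulator classes** — hubs draw a truncated power-law out-degree
  (`P(k) ∝ k^-gamma_target` on `k_min_hub..N-1`, defaults 2.3 and 8) and
  target a *contested core pool* sized `pool_mult` (default 0.85) times
  the number of active TFs; selective regulators (probability
  `p_selective`, default 0.5) have out-degree 1–3 and target uniformly,
  creating private (in-degree-one) targets. The contested core plus
  private targets is what produces non-trivial critical and redundant
  edge fractions; with uniform targets alone every edge of such a network
  is ordinary, because a dense random bipartite graph is an expander in
  which any deleted matched edge can be re-routed.
* **Sequential activation** — TFs consume their drawn out-degree from the
  edge budget until exactly `L` edges are placed. The number of *active*
  regulators therefore scales with `L`, which reproduces the empirical
  signature of real cohorts: driver fractions in roughly `[0.70, 0.94]`
  and a strong negative density–`n_D` correlation (about −0.8 on default
  cohorts).
* **Cohort envelopes** — `default_cohort_phases()` draws 3/5/7/25
  networks for phases 1–4 with node counts, average degrees and edge
  counts bounded by the per-phase ranges of the packaged 40-network
  table (N 259–584, average degree 1.37–6.20, L 465–2711).
* **Expression** — `generate_expression()` draws negative-binomial counts
  per (gene, network-sample) with hub TFs given elevated means, so the
  Critical/HO/HE categories overlap non-trivially.

Everything is a pure function of its seed; cohorts and expression tables
derive per-item child seeds from one master seed.

What passing tests on these networks do **not** show: the generator makes
no attempt to reproduce the published table's redundant-edge fractions
quantitatively (synthetic `l_r` is around 0.1; real networks reach 0.6),
nor transfer-entropy edge semantics, pseudotime structure, or
single-cell count matrices. Conclusions about biology require the real
inferred networks; the synthetic cohort demonstrates that the machinery
measures what it claims to measure, with planted parameters recovered
within stated tolerances (e.g. a planted exponent of 2.3 recovered in
`[2.0, 2.6]` across 20 configuration-model draws of 2000 degrees).

## Numerical choices and degenerate inputs

* Self-loops are dropped (with a warning) and duplicate edges collapsed at
  construction: driver counts and edge-class fractions are defined on
  simple directed graphs.
* Gene symbols are matched exactly and case-sensitively (zebrafish
  `sox2` is not mouse/human `SOX2`); sorting uses C-locale radix order
  for determinism.
* Isolated nodes are supported via an explicit node list (and node
  sidecar files in I/O): density and `n_D` depend on `N` including
  degree-zero nodes, and whether a printed `N` counted isolated nodes
  cannot be settled from a table alone — the sidecar mechanism covers
  both readings.
* Edgeless networks: `gcc_fraction` is `1/N`; classification and the
  removal curve require `L >= 1`; correlation helpers refuse constant
  variables rather than returning `NaN`.
* All-tied Kruskal–Wallis input yields statistic 0 with a warning (the
  tie-corrected denominator vanishes).
* Hub rankings break outdegree ties lexicographically, so top-k lists are
  stable across runs.

## Problem sizes used in the shipped checks

The test suite classifies networks up to the largest published scale
(N = 503, L = 2711 in a single network; full 40-network cohorts up to
N = 584) and runs its exhaustive matching oracle on 400 random graphs of
up to 10 edges, where enumeration over all 2^L edge subsets is exact.
Robustness checks use 20 permutations on networks of 60–100 nodes;
degree-exponent recovery uses 20 seeds at 2000 nodes. These sizes were
chosen so the full suite exercises every code path at published scale
while remaining quick enough to run on every change.

## Known limitations

* Structural controllability ignores edge weights and dynamics; a
  network can be structurally controllable yet practically
  uncontrollable for energetic reasons. Control-energy analysis is out
  of scope.
* The CCDF regression estimator for `gamma` is simple and comparable
  across networks but statistically inefficient; its sampling spread at
  a few hundred positive degrees is several tenths.
* `analyze_cohort()` treats each network independently; real cohort
  networks are overlapping subgraphs of one regulatory network
  (`network_overlap()` quantifies this), so cohort-level p-values should
  be read descriptively, not as independent-sample inference.
* The Venn partition reports categorised TFs only; a TF absent from all
  three categories in every network does not appear.
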