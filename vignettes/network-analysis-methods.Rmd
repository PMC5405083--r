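---
title: "Methods: weighted connectivity graphs, spanning trees, and group comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectivity graphs, spanning trees, and group comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmst)
```

## The analysis in one paragraph

`fcmst` analyses regional brain signals as weighted undirected graphs.
Each subject contributes a frames-by-ROIs time-series matrix; pairwise
Pearson correlations between ROI signals form a symmetric weighted
adjacency matrix $w_{ij}$, with negative correlations discarded (set to
exact zero, the no-edge weight) and the diagonal stored as zero. On this
graph the package computes a small-world panel against random null
ensembles, extracts the maximum-weight spanning tree and its descriptors,
profiles hub regions across a population, correlates nodal tree metrics
with behavioural response times, and compares groups with FDR-corrected
one-way unbalanced ANOVAs. A synthetic-cohort generator reproduces the
statistical structure each stage assumes, so the full chain is testable
without restricted neuroimaging data. The canonical parcellation shipped
with the package is the 28-lobule cerebellar atlas; excluding the tiny
Vermis Crus I lobule leaves 27 ROIs and at most $27 \cdot 26 / 2 = 351$
edges per graph.

## Small-world panel

For weights normalized by their maximum, $\hat w = w / \max(w)$, the
triangle intensity around node $i$ is

$$t_i = \tfrac{1}{2} \sum_{j,k} (\hat w_{ij} \hat w_{jk} \hat w_{ki})^{1/3},
\qquad
C_i = \frac{2 t_i}{k_i (k_i - 1)},$$

the geometric-mean (Onnela) weighted clustering coefficient, with $k_i$
the binary degree and $C_i = 0$ when $k_i < 2$. The max-normalization
keeps $C_i \in [0, 1]$ and makes clustering invariant to a global
rescaling of the weights. Distances use reciprocal edge lengths
$1 / w_{ij}$ — the standard convention for correlation weights, where a
strong correlation is a short functional hop — and the characteristic
path length $L_w$ is the mean Dijkstra distance over ordered pairs.
Connectivity cost is the mean off-diagonal weight.

Null models preserve both the degree sequence and the multiset of edge
weights: Maslov–Sneppen double-edge swaps carry each weight along with
its edge. The defaults are 100 nulls and 10 swap attempts per edge per
null. Ensemble means give $\gamma = C_w / C_w^{rand}$,
$\lambda = L_w / L_w^{rand}$, and the small-worldness index
$\sigma = \gamma / \lambda$, which exceeds 1 for networks combining
high segregation with near-random integration. Two degenerate regimes
are handled explicitly: a complete graph admits no rewiring (the nulls
equal the input, with a warning, and $\sigma = 1$ by construction), and
disconnected graphs raise an error unless the harmonic-mean path-length
fallback is requested, in which case the result is labelled as such.

## Maximum-weight spanning tree

Thresholding weighted graphs biases group comparisons; the spanning tree
that maximizes total weight summarizes each subject's strongest
connections with a fixed edge budget of $n - 1$. Kruskal's algorithm runs
on ascending reciprocal weights with union–find cycle rejection.
Tie-breaking is deterministic by $(-w, i, j)$ lexicographic order so runs
are bit-reproducible; equal-weight edges are reported because the
maximizer is then not unique (this never occurs for continuous
correlation weights, but does for hand-built test graphs).

Local descriptors are hop-based on the tree: degree, betweenness as the
fraction of the $(n-1)(n-2)/2$ unordered pairs whose unique path crosses
the node (so a star centre attains exactly 1), and eccentricity. Degree
and betweenness are additionally normalized by their within-tree maxima;
eccentricity, diameter $d$ (max eccentricity) and radius $r$ (min
eccentricity) are normalized by $n - 1$, the longest possible tree path.
The tree never states which normalization its published magnitudes use,
and max-normalized eccentricity would force $d = 1$ always; the
$(n-1)$-scale is the one consistent with diameters of order 0.3–0.4 for
27-node trees.

Global descriptors: leaf fraction $L_f = N_{leaf} / (n - 1)$; tree
hierarchy $T_h = N_{leaf} / (2 (n-1) BC_{max})$, which balances diameter
reduction against hub overload and approaches 0.5 for the optimal
(star-like) configuration — exactly 0.5 for a star, since $L_f = 1$ and
$BC_{max} = 1$; degree divergence $\kappa = \langle k^2 \rangle /
\langle k \rangle$ on raw degrees (normalized degrees would shrink the
published 2.2–2.3 range for 27 nodes); and degree correlation $r_{deg}$,
the Pearson correlation of endpoint degrees over both orientations of
every edge, which makes a star's value $-1$ rather than undefined.
$r_{deg}$ is reported as missing below 3 nodes.

## Hubs and response-time correlations

A subject's hub is the ROI attaining the maximum normalized betweenness
(or degree) of its tree; the population hub profile is the per-ROI
fraction of subjects peaking there. Ties credit every tied ROI, so
fractions may sum above 1; since argmax is invariant under the positive
per-subject normalization, raw and normalized metrics give identical
profiles. Per-ROI Pearson correlations between a tree metric and median
response time (MRT) use two-sided t-tests on $n - 2$ degrees of freedom,
reported unadjusted (an optional BH family across ROIs is available);
the selected region is the one with the largest *positive* correlation,
with a flag for largest absolute value.

## Group statistics

Metric panels are right-skewed in general, so inference runs on
$\ln(x + 10^{-24})$; the tiny constant only guards exact zeros. The
degree correlation is the one negative-valued metric, so it is shifted by
+1 before the transform (mapping $(-1, 1]$ to $(0, 2]$), recorded in the
output; per-metric transforms can be disabled. Each contrast is a classic
pooled-variance one-way ANOVA on two groups of unequal size ("unbalanced"
names the design, not a Welch correction). The five standard contrasts
are low vs high IQ overall, low vs high within each gender, and male vs
female within each IQ group. BH correction at $\alpha = 0.05$ is applied
across the metric family *within* each contrast; pooling all contrasts
into one family is a defensible alternative and available by adjusting
the returned raw p-values, but the per-contrast family is the default.
Group means and SDs are always reported on the original metric scale.

IQ groups follow the printed interval rule: scores 4–10 are "low", 22–24
"high", score 3 excluded, the rest "mid". A quantile-based rule (median
± one quartile) is not applied automatically because the published lower
quartile (≈6) is inconsistent with the 25th percentile of a left-skewed
distribution with median 16; the printed intervals are treated as
authoritative.

## The synthetic cohort generator

The generator emulates the study conditions: 27 ROIs, 1200 frames at a
0.72 s sampling interval, four correlation modules with within/between
module correlations 0.3/0.1, an optional hub ROI whose correlations are
raised by +0.25 (clipped below 1), per-group multipliers for planting
clustering/density differences, a left-skewed discrete IQ score
($27 - \mathrm{Poisson}(11)$, truncated to $[3, 27]$, median ≈ 16, both
tails populated), a 60% female proportion, and lognormal MRT marginals
(meanlog $\log 8000$ ms, sdlog 0.3 — the per-subject MRT marginal is not
published, so this is a free, documented choice of a plausible
reasoning-task scale). Targets that lose positive semi-definiteness
(e.g. through a large hub boost) are repaired by eigenvalue clipping and
re-normalization to unit diagonal, with a warning and a recorded flag;
targets with an eigenvalue below $-0.5$ are rejected as misconfigured.
Frames are i.i.d. multivariate Gaussian by default; optional AR(1)
smoothing uses variance-preserving scaling so the cross-sectional
correlation target is untouched. BOLD autocorrelation is irrelevant to
correlation-matrix expectations, which keeps the generator's oracles
exact.

The planted metric–MRT link deserves a note. For linked subjects the MRT
is linear in the standardized metric value at the planted ROI,
$\mathrm{MRT} = \mu + s\,(\rho z + \sqrt{1-\rho^2}\,\varepsilon)$, with
$\mu, s$ matched to the lognormal marginal's mean and SD. A
copula-through-the-exponential construction was rejected: tree
betweenness is right-skewed and discrete, and mapping it through an
exponential link aligns the heavy tails and inflates the realized
Pearson correlation well above the nominal $\rho$, whereas the linear
construction plants exactly $\rho$. The cost is that the linked group's
marginal is approximately normal rather than lognormal.

Two features of real data are deliberately not modelled: scanner/motion
artifacts, and broad, heavy-tailed correlation spectra. The latter means
sampled connectivity matrices are usually *complete* (at 1200 frames,
between-module correlations of 0.1 essentially never come out negative),
so on simulated cohorts the null ensemble degenerates and the
small-world stage is uninformative — passing pipeline tests demonstrate
bookkeeping and determinism there, not small-world recovery. For
small-world behaviour the package provides `modular_weight_graph()`: all
within-module edges at weight 0.6, a small fraction (5%) of
between-module pairs carrying a strong shortcut at the same weight, and
weak 0.1 edges on 20% of the remaining cross pairs. The shortcuts are
essential, not cosmetic: with reciprocal edge lengths, a modular graph
whose only inter-module ties are weak bridges has $\lambda \gg 1$ and is
*not* small-world, while strong sparse shortcuts are precisely the
Watts–Strogatz mechanism that keeps $\lambda \approx 1$ while clustering
stays high. With these defaults $\sigma$ lands around 1.3–1.5 with mean
connectivity cost ≈ 0.16, comfortably in the small-world regime.

## Numerical choices and degenerate inputs

- Zero-variance ROI signals abort connectivity with the ROI named.
- Graphs whose positive-weight subgraph is disconnected abort tree
  construction with the component sizes listed.
- ANOVA with zero pooled within-group variance returns $F = 0, p = 1$
  for equal means and $F = \infty, p = 0$ (flagged degenerate) otherwise.
- Constant metric columns are reported as missing correlations; a
  constant MRT vector is an error.
- `hub_fractions()` treats values within $10^{-8}$ of the row maximum as
  tied.
- All stochastic stages accept explicit seeds; a cohort is bit-identical
  under a fixed configuration seed.

## Problem sizes used by the test suite

The suite validates the graph primitives against brute-force oracles
(exhaustive simple-path enumeration, spanning-tree enumeration,
triple-loop clustering, hand-walked tree paths) on 200 random graphs of
6–8 nodes; statistical calibration uses 200 replicate two-group panels
of 40 + 40 subjects and 10 metrics, checking a BH rejection rate ≤ 7%
under the null and ≥ 80% detection of a 1-SD connectivity shift; and
parameter recovery uses 20 replicate cohorts of 70 + 70 subjects at the
full 27-ROI, 1200-frame geometry, requiring the planted hub and the
planted $\rho = 0.5$ MRT ROI to be recovered in at least 90% of cohorts.

## Known limitations

- The package starts from ROI time-series (or a labelled volume plus a
  4D image); registration, segmentation, and denoising are upstream and
  out of scope.
- Binary-graph metrics, efficiency/modularity, rich-club and
  participation coefficients are not implemented.
- The small-world panel requires a rewirable (non-complete) graph to be
  informative.
- Published headline group statistics depend on restricted subject data
  and cannot be reproduced from synthetic cohorts; the package instead
  guarantees the structural identities and statistical calibration
  described above.
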