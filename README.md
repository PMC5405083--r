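# fcmst

Graph-theoretical analysis of regional brain signals: weighted
functional-connectivity networks, small-world indices against null
ensembles, maximum-weight spanning trees and their descriptors, hub
profiling, response-time correlations, and FDR-corrected group
comparisons — with a synthetic cohort generator so the whole pipeline
runs and is tested without access to restricted neuroimaging data.

The package is aimed at researchers analysing ROI-level resting-state
fMRI (the shipped parcellation is the 28-lobule cerebellar atlas, 27
ROIs after excluding the tiny Vermis Crus I), but every stage works on
any frames × ROIs signal matrix.

## The method

Per subject, the connectivity matrix is the pairwise Pearson correlation
between ROI signals, with negative values discarded (w = 0 means "no
edge") and zero diagonal. On this weighted graph:

- **Small-world panel** — geometric-mean (Onnela) weighted clustering
  C_w on max-normalized weights; characteristic path length L_w with
  reciprocal edge lengths 1/w; connectivity cost (mean off-diagonal
  weight); and, against an ensemble of 100 degree- and weight-preserving
  Maslov–Sneppen surrogates, γ = C_w/C_w^rand, λ = L_w/L_w^rand, and the
  small-worldness index σ = γ/λ (σ > 1 for small-world organization).
- **Maximum-weight spanning tree** — Kruskal with union–find and
  deterministic tie-breaking retains the n−1 strongest connections.
  Local descriptors: degree, betweenness (fraction of node pairs whose
  unique path crosses the node), eccentricity. Global descriptors:
  diameter, radius, leaf fraction L_f = N_leaf/(n−1), tree hierarchy
  T_h = N_leaf/(2(n−1)·BC_max) (0.5 at the optimum), degree divergence
  κ = ⟨k²⟩/⟨k⟩, and degree correlation r_deg (assortativity).
- **Hubs & response times** — per-ROI fraction of subjects whose tree
  betweenness/degree peaks there; per-ROI Pearson correlation between a
  tree metric and median response time, with the best positive region
  selected.
- **Group statistics** — natural-log transform (ln(x + 1e−24); r_deg is
  shifted +1 first), classic one-way unbalanced ANOVA for each of five
  group/gender contrasts, Benjamini–Hochberg FDR at 0.05 within each
  contrast's metric family.

See the methods vignette (`vignettes/network-analysis-methods.Rmd`) for
formulas, defaults, and design rationale.

## Worked example

```r
library(fcmst)

# a clustered modular weighted network and its small-world panel
g <- modular_weight_graph(seed = 7)
sw <- small_worldness(g, n_null = 100, seed = 11)
sw
#> Small-world panel (100 nulls):
#>   C_w = 0.4164  L_w = 4.0123  conn = 0.1618
#>   gamma = 1.9409  lambda = 1.2722  sigma = 1.5257
```

The network keeps its clustering almost twice as high as its rewired
surrogates (γ ≈ 1.9) at only modestly longer paths (λ ≈ 1.3), so
σ ≈ 1.5 > 1: small-world organization.

```r
# a synthetic 24-subject cohort with a hub planted at ROI 5
cfg <- cohort_config(c(low = 12, high = 12), seed = 42, hub_roi = 5)
cohort <- simulate_cohort(cfg)
res <- run_pipeline(cohort = cohort, small_world = FALSE)

res$hub_profiles[["low.degree"]]
#> Hub profile over 12 subjects; top ROIs:
#> ROI5 ROI1 ROI2 ROI3 ROI4
#>    1    0    0    0    0

head(res$metric_table[, c("subject_id", "group", "conn", "d", "l_f",
                          "t_h", "kappa", "r_deg")], 4)
#>       subject_id group   conn      d    l_f    t_h   kappa   r_deg
#> S0001      S0001   low 0.1607 0.1538 0.9231 0.4644 11.6923 -0.8664
#> S0002      S0002   low 0.1662 0.1538 0.8846 0.4492 10.0769 -0.7576
#> S0003      S0003   low 0.1553 0.1923 0.8846 0.4520 10.0769 -0.7645
#> S0004      S0004   low 0.1650 0.1538 0.8077 0.4102  9.2692 -0.6913
```

Every low-IQ subject's maximum tree degree lands on the planted hub
(fraction 1 at ROI 5), and the hub-dominated trees are star-like: leaf
fractions near 0.9, tree hierarchy near the 0.5 optimum, strongly
negative assortativity. The contrast table
(`res$comparisons`) reports per-metric group means ± SD on the raw
scale with F, p, and BH-adjusted p; with no planted group effect,
nothing survives correction:

```r
subset(res$comparisons, contrast == "low_vs_high",
       c(metric, mean_a, mean_b, F, p, p_fdr))
#>  metric  mean_a  mean_b      F      p  p_fdr
#>     c_w  0.2518  0.2596 4.2995 0.0500 0.3042
#>     l_w  4.6799  4.6170 3.6956 0.0676 0.3042
#>    conn  0.1619  0.1656 2.7208 0.1133 0.3398
#>    ...
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run-analysis.R --config cohort.yaml --out results/ --seed 7
```

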