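---
title: "Methods: pseudo-bulk time-course analysis along pseudotime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-bulk time-course analysis along pseudotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Trajectory inference orders single cells along a developmental path and
assigns each cell a *pseudotime* — its distance from a chosen root. The
scientific question that follows is which genes change expression along
that path. Testing at the level of individual cells treats every cell as
an independent replicate, which it is not: cells from one animal share
biological and technical effects, and the resulting p-values are badly
anti-conservative. pseudotempo instead aggregates cells into
**pseudo-bulk profiles** — one column of summed counts per
(biological sample, cell cluster) combination — and performs bulk-style
negative-binomial inference on those, with the sample of origin as a
blocking factor. Replication now lives at the level the experiment
actually randomized.

## The model

For gene $g$ and pseudo-bulk sample $j$ with effective library size
$N_j$ (library size times TMM factor), counts are modelled as

$$y_{gj} \sim \mathrm{NB}(\mu_{gj},\ \phi_g), \qquad
  \log \mu_{gj} = \beta_{g0} + \sum_{k=1}^{3} \beta_{gk} Z_k(t_j)
  + \gamma_{g,s(j)} + \log N_j,$$

where $t_j$ is the mean pseudotime of the member cells, $s(j)$ the
biological sample (developmental stage; the earliest stage is the
reference absorbed into the intercept), and $\mathrm{Var}(y) = \mu +
\phi\mu^2$ defines the NB dispersion $\phi$ (BCV $= \sqrt{\phi}$).

The pseudotime covariates $Z_1, Z_2, Z_3$ come from a natural cubic
spline re-parametrized for interpretability: form $A = [\,1,\ t,\
\mathrm{ns}(t, \mathrm{df}=3)\,]$, orthonormalize its columns in that
order by QR decomposition with the positive-diagonal sign convention,
and drop the first (intercept) direction. Because $t$ precedes the
spline columns — and because the linear function is itself a natural
spline, making $A$ exactly rank $\mathrm{df}+1$ — the first retained
coordinate is exactly

$$Z_1 = \frac{t - \bar t}{\lVert t - \bar t \rVert},$$

so the sign of a gene's $Z_1$ coefficient says whether its expression
generally rises (`Up`) or falls (`Down`) along the trajectory, while
$Z_2, Z_3$ capture orthogonal curvature. Internal knots sit at equally
spaced quantiles of $t$ (linear-interpolation quantile definition; the
1/3 and 2/3 quantiles for df = 3); `df` between 3 and 5 is reasonable
when the residual degrees of freedom allow, and df = 3 is the default —
no automatic selection is attempted.

## Inference

**Dispersion estimation** (`estimate_dispersions()`) maximizes the
Cox–Reid adjusted profile likelihood (APL): the NB log-likelihood at the
per-gene IRLS solution minus $\tfrac12 \log\det(X^\top W X)$, which
corrects the profile likelihood for the coefficients estimated per gene.
Three estimates are kept: a *common* value (summed APL over all genes),
a *trended* value (per-abundance-bin APL maxima, smoothed over average
log2-CPM by monotonicity-preserving cubic interpolation and clamped
outside the bin range), and *tagwise* values from a weighted-likelihood
empirical-Bayes rule (per-gene APL plus `prior_n = 10` times the
moving-average APL of abundance neighbours, maximized on a shared
$2^{[-6,6]}$ grid around the trend). Only the **trended** dispersion
enters the QL fit; tagwise values exist for the BCV diagnostic plot.

**Quasi-likelihood fit** (`ql_fit()`). With $\phi_g$ fixed at the trend,
gene-specific variability is captured by the QL dispersion
$s^2_g = D_g / d_g$ (residual deviance over residual df; df is $n - p$
reduced by the number of effectively-zero fitted values). The $s^2_g$
are squeezed toward an abundance trend by empirical Bayes: on the
log scale the $s^2$ are debiased by $\psi(d/2) - \log(d/2)$, a lowess
trend over average log2-CPM is fitted, and the prior df $d_0$ comes from
inverting the trigamma function on the excess variance of the residuals
(a scaled-F prior by moment matching). The posterior value is the
df-weighted average $(d_0 s_0^2 + d\,s^2)/(d_0 + d)$. With
`robust = TRUE` the moment matching winsorizes residuals at the 5th and
95th percentiles, and genes above the upper limit get an exponentially
reduced per-gene prior df (floored at 1), so hypervariable outliers are
not shrunk into false significance.

**Testing** (`ql_f_test()`). The quasi-F statistic is the
drop-in-deviance between the null refit (tested columns removed, same
trended dispersions) and the full fit, divided by the number of tested
coefficients and by the squeezed QL dispersion, referred to
$F(r,\ d_g + d_{0g})$. Testing $\{Z_1, Z_2, Z_3\}$ jointly asks "does
expression change along pseudotime at all"; re-testing $Z_1$ alone gives
the directional split used for enrichment. Coefficients are reported in
log2 units; multiplicity is controlled by Benjamini–Hochberg.

**Enrichment** (`directional_ora()`). Up and Down gene lists are tested
against GMT collections by one-sided hypergeometric upper-tail p-values,
with sets intersected with the analysis universe (genes surviving the
expression filter with a valid identifier) first. Raw p-values are
reported, as is conventional for this test; a BH column is available
behind `adjust = TRUE`. Gene-set retrieval, GO graph propagation and
abundance-bias correction are out of scope.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_cells` (basic_filter) | 3 | cells a gene must be expressed in |
| `min_features` | 200 | expressed genes a cell must have |
| `min_genes`, `max_genes`, `max_mito` | 500, per-sample, 10 | QC bounds, all **strict** inequalities |
| `min_cells` (filter_small) | 30 | pseudo-bulk kept iff cell_number **> 30** |
| `min_count`, `min_total` | 10, 15 | expression filter (CPM rule at median library) |
| `logratio_trim`, `sum_trim` | 0.30, 0.05 | TMM trim fractions on M and A |
| `prior_count` | 2 | log-CPM prior, scaled to each effective library |
| `df` | 3 | spline degrees of freedom |
| `prior_n` | 10 | tagwise dispersion shrinkage weight |
| `alpha` | 0.05 | FDR threshold for calls |

The strict boundaries mirror the analysis code this workflow
standardizes (a cell with exactly 500 genes, exactly 10% mitochondrial
reads, or a pseudo-bulk with exactly 30 cells is removed), and the
pseudo-bulk naming `<sample>_C<cluster>` matches the reference tables
shipped in `mammary_pseudobulk_info()` so printed tables can be diffed
by name.

## The synthetic-data generator

`simulate_cells()` emulates the structure of a five-stage developmental
10x experiment: per-sample clusters occupy overlapping windows along a
single trajectory of length 40 pseudotime units; gene means are
$\mu = L_c \cdot p_{gc}$ with $p_{gc} \propto \mathrm{base}_g
\exp(f_g(t) + s_{g,\mathrm{sample}})$; counts are NB with gamma-mixed
per-gene dispersions (mean 0.1 at the cell level). Ten percent of genes
carry monotone trends (linear, sigmoid or smoothstep; total natural-log
fold change 2.5 across the trajectory, split evenly up/down), per-sample
effects have SD 0.1 on the log scale, 5% of reads are mitochondrial in
healthy cells (30% in the 2% planted dead cells), and 5% of barcodes are
doublets formed by summing two recorded parents. These defaults were
chosen once to resemble a well-powered multi-stage atlas and are frozen;
the stochastic end-to-end test runs at a fixed seed under exactly these
conditions. `simulate_pseudobulk()` generates at the replicate level
directly (preset `"mammary"` reproduces the 22 retained reference
pseudotimes and stages) and is the fast route for calibration checks.

What the generator does *not* emulate: zero inflation beyond NB,
branching trajectories, ambient RNA, batch chemistry effects, or
misassigned clusters. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to
every artefact of real data.

## Numerical choices

- IRLS for the NB GLMs runs to relative deviance tolerance 1e-8 (50
  iterations max) with step halving; linear predictors are clamped to
  ±30 and the normal equations carry a 1e-10 ridge. Fits are compiled
  (RcppArmadillo), which keeps a 2000-gene dispersion estimation in
  seconds.
- APL maximization is derivative-free 1-D optimization on
  $\log \phi \in [\log 10^{-6}, \log 10]$, tolerance 1e-6.
- The dispersion-abundance trend uses equal-size rank bins
  (≈50 genes minimum, ≤20 bins) and `monoH.FC` interpolation of
  log-dispersion, constant beyond the outer bin centres.
- Ties in `top_table()` break by larger F then gene name, so output is
  invariant to input row order.
- TMM's depth invariance is asymptotic, not exact: the inverse-binomial
  weights do not scale uniformly when one library is uniformly scaled
  (the shift is ~0.005 on typical data and identical in the reference
  implementation); tests assert it at that scale.
- Log-CPM's prior count is pinned to the *average* effective library,
  so global depth scaling moves zero-count genes slightly; the exact
  invariance holds when the prior is scaled along with the depth.
- `heatmap_matrix()` rejects constant rows rather than emitting NaN.
- Fitted curves use the raw-basis fit (`design_raw`), averaging group
  effects with an implicit 0 for the reference stage, and add
  $\ln 10^6$ only (population-level CPM) — the library-size offset is
  deliberately excluded, and no per-sample normalization enters the
  curve.

## Design choices made where the design was open

- Mean (not median) pseudotime summarizes each pseudo-bulk sample;
  `summarise_pseudotime = "median"` is exposed since the choice is not
  critical.
- Aggregation runs on raw merged counts; gene filtering happens at the
  pseudo-bulk level afterwards, so cell-level gene filters cannot
  silently change pseudo-bulk totals.
- Cells with non-finite pseudotime (unreachable on the trajectory
  graph) are refused by `aggregate_cells()` rather than dropped, forcing
  the caller to make that exclusion explicit.
- Downstream joins key on gene symbol (rows are renamed to symbols
  after first-occurrence de-duplication), with Ensembl and Entrez ids
  carried alongside.
- The enrichment universe is the post-filter, identifier-valid gene
  set.
- Pipeline reuse detection hashes the configuration and every input
  file into the run manifest and skips recomputation when nothing
  changed; per-stage object caching was rejected to keep runs fully
  reproducible from text inputs alone.

## Known limitations

- The QL F-test is mildly conservative at high dispersion with ~22
  samples (rejection ≈ 0.03 at nominal 0.05 for $\phi = 0.5$), matching
  the reference implementation's behaviour under identical data; the
  small-sample adjusted-deviance corrections that address this are out
  of scope.
- Single-trajectory only: branch-specific tests and trend-shape
  clustering are not provided.
- Doublet *scoring* is consumed as an input flag, never computed.
- The dispersion trend assumes enough genes (≥ ~100) to bin; tiny
  panels fall back to a constant trend.

## Problem sizes used by the test suite

Unit and property tests run at 100–2000 genes; the statistical
calibration tests use 2000 genes × 22 pseudo-bulk samples per dispersion
setting, and the end-to-end recovery test simulates 2000 genes ×
~1260 cells (5 samples × 4 clusters × 60 cells plus doublets). These
sizes make every distributional check well-resolved while keeping the
default suite runtime around a minute of compute for the statistical
blocks.
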