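---
title: "Histoepigenetic analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histoepigenetic analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoepi)
```

# The problem

Bulk tumor assays measure a mixture. If a sample is 70% cancer cells and
30% stroma, its bulk expression of a gene is (to first order) the
proportion-weighted sum of the gene's level in each constituent cell
type. Tumor purity varies widely between samples, so ranking samples by
bulk expression of a gene largely ranks them by purity whenever the gene
is expressed predominantly in one compartment. `histoepi` separates the
two signals: it estimates per-sample cell-type proportions from DNA
methylation, conditions expression analysis on those proportions, and
groups samples by the gene's level *within cancer cells*.

# Stage 1: deconvolution

## Methylation factorization

The model is `B ≈ M P` for a beta-value matrix `B` (probes × samples),
cell-type profiles `M` (probes × k, entries in `[0, 1]`) and proportions
`P` (k × samples, columns on the probability simplex). The fit minimizes
the Frobenius residual by alternating two *exact* constrained
least-squares steps, each solved by a small active-set quadratic program
(compiled code; KKT residuals below 1e-8):

* P-step: per sample, least squares under nonnegativity and sum-to-one;
* M-step: per probe, least squares under the box `[0, 1]`.

Each half-step is an exact minimizer, so the residual sum of squares is
non-increasing — asserted per iteration in the unit tests. Convergence is
declared when the relative RSS change falls below `tol` (default 1e-6,
cap 2000 iterations). Because the objective is biconvex, not convex, the
best of `nRestarts = 10` random restarts is kept (initial proportions
Dirichlet(1)); when reference profiles are available the first restart
is seeded by regressing `B` on them, which in practice lands in the
global basin immediately. The factorization is identifiable only up to
column permutation; every downstream comparison goes through
`matchCellTypes()`, which maximizes total Pearson correlation under a
one-to-one assignment (ties broken by column index and flagged when the
best and runner-up scores are within 1e-6).

Informative probes are chosen one-vs-rest: per reference class, a
two-sample Welch t test of that class against the others per probe
(threshold p < 1e-5, default 500 probes taken round-robin across classes
ranked by absolute mean beta difference). With a single profile per
class there is no within-class variance, and the selection falls back to
pure effect-size ranking, with a message.

The number of cell types is chosen by bootstrap stability: for each
candidate k, samples are resampled `nBoot = 10` times, each resample is
factorized, and the score is the mean matched-column correlation of the
estimated `M` across all pairs of resamples; the selected k is the
largest candidate scoring at least 0.9. The resampling scheme and the
matched-correlation statistic are this package's definitions — the
bootstrap-stability idea admits many variants and results should be
compared only within one definition.

## Expression regression

Given fixed `P`, each gene's bulk profile is regressed on `P` under a
nonnegativity constraint (expression cannot be negative; an unconstrained
option exists because the constraint biases estimates near zero).
Standard errors use the ordinary-least-squares covariance formula with
`ν = n − k` even when a nonnegativity constraint is active — the
active-constraint entries are flagged instead of given special variance
treatment, keeping the error model simple and transparent. Expression
stays on the *linear* scale here because mixing is linear; log
transforms appear only in the network stage.

## Gene-centered grouping

The iterative group fit alternates (a) within-group estimation of the
gene's cell-type profile and (b) reassignment of every sample to the
group whose profile predicts its observed bulk value of the gene more
closely. The distance is the scalar `|predicted − observed|` on the gene
of interest only; a multi-gene Euclidean option exists but is off by
default, because grouping on one gene is the method's point and extra
genes dilute the signal. Exact distance ties keep the sample's current
group, which prevents oscillation. A group shrinking to k or fewer
samples (too few for the regression) triggers a fresh random split, at
most 10 times.

Consensus: 3 independent runs (odd, for strict majority), aligned by the
estimated cancer-cell level of the gene — the group with the higher
level is "high" — then a per-sample majority vote. The cancer cell type
is taken from `matchCellTypes()` labels; if none is designated, the cell
type with the maximal pooled expression of the gene is used and logged.
Recursive partitioning re-splits the low group, yielding depth + 1
ordered groups; the natural comparison is first versus last.
`tercileConcordance()` compares two sample rankings by their top and
bottom thirds (bin size `floor(n/3)`, remainder to the middle, ties
resolved by sample ID).

# Differential expression and enrichment

Between-group comparison per gene and cell type uses
`t = (mean_hi − mean_lo)/√(se_hi² + se_lo²)` with Welch–Satterthwaite
degrees of freedom over the two groups' residual dofs (a `"sum"` option
gives `ν_hi + ν_lo`). Calls require both FDR q < 0.05
(Benjamini–Hochberg across genes) and fold change ≥ 2. Genes with a zero
mean in one group get a half-minimum pseudo-value for the fold change
and a flag, so the FC filter stays applicable. Set overlaps are scored
by the upper-tail hypergeometric probability.

# Stage 2: the gene network

Variables are `log2(expression + 1)` for the selected genes plus the
cell-proportion rows as covariate-flagged nodes, all standardized; the
sparse precision matrix is estimated by the graphical lasso on their
correlation matrix. The graphical lasso here is this package's own
implementation (block coordinate descent, off-diagonal penalty, diagonal
of the working covariance fixed at `S_jj + λ`); it is validated in the
test suite against the KKT optimality conditions of the penalized
likelihood, the two-variable soft-threshold closed form, and the
`λ → 0` matrix-inverse limit. Exact zeros in the precision matrix are
structural zeros (non-edges).

All k proportion rows are included as covariate nodes by default. The
rows are collinear on the simplex; the ridge-like effect of the penalty
tolerates this, and a `"drop-one"` option removes the last cell type for
users who prefer a full-rank design. After fitting, covariate nodes and
their edges are removed *without refitting*, so the reported gene–gene
partial correlations are still conditioned on composition.

Penalty selection follows StARS: `nSubsamples = 20` subsamples of size
`⌊10√n⌋`, per-edge instability `2f(1−f)` averaged over all pairs,
monotonized along the decreasing-λ path, selected λ = smallest penalty
with instability ≤ 0.05. A fixed-λ override bypasses selection for
reproducing a previously chosen penalty (e.g. 0.125). Edge weights are
the signed partial correlations; the strong-edge rule flags weights
exceeding the mean of the *existing* (nonzero) edge weights by at least
one standard deviation — zero entries of a trimmed network are
non-edges, not weights, so they are excluded from the statistics.

Connectedness of a node set is scored by a permutation statistic: the
induced-subgraph edge count against the edge counts of uniformly random
node sets of the same size, `p = (1 + #{null ≥ obs})/(nPerm + 1)`. This
is a deliberate replacement for encoding-length module statistics: it is
simple, exactly calibrated by construction, and sufficient for
positive/negative-control designs. Its p-values are mildly conservative
on sparse graphs where the edge count takes few distinct values — a
calibration check against the uniform distribution is only meaningful
when the background graph is dense enough for the statistic to spread
(the test suite uses size-21 query sets on a 100-node density-0.3
background for exactly this reason).

# The simulator

`generateReferencePanel()` builds k separable methylation archetypes —
block-structured bimodal betas drawn near (not at) 0 and 1, truncated so
the between-class gap is at least 0.7, mirroring the bimodality of real
450K reference profiles — and matched expression profiles with two
cancer variants that share the cancer methylation archetype and differ
only in the variant gene (default 10-fold, cancer-low level 10).
`simulateMixtures()` draws one Dirichlet(1) proportion vector per sample
and uses the *same vector* for the methylation and expression mixtures
(the defining coupling of matched bulk data); each cancer variant
contributes 50 mixtures by default. Methylation noise resamples each
reference beta from a Beta distribution with matching mean and
concentration `s = 100` — mean-preserving and support-respecting; the
concentration is a package default, chosen so per-probe noise has
standard deviation of a few percent, as no canonical value exists.
Expression mixing is deterministic by default (an optional Poisson
resampling exists for stress tests).

What passing tests on this simulator do **not** show: robustness to
array normalization artifacts, probe cross-reactivity, reference panels
that imperfectly represent the tumor's constituent cells, count
overdispersion in RNA-seq, or cell types absent from the reference —
real-data performance depends on all of these.

# Validation design and problem sizes

The validation experiments (test suite and `scripts/acceptance.R`) use:
noiseless k = 3 mixtures (120 probes, 40 samples) for exactness; a
4-reference, 2-variant, 100-mixture design with beta noise `s = 100` for
paper-style recovery; 20 repeated splittings for grouping stability;
200-gene/30-per-group simulations with planted 2.5-fold cancer-cell
changes (multiplicative lognormal noise, sd 10% of the mean) for
sensitivity and FDR; and 1000-gene null simulations for type-I
calibration. The null simulation uses per-gene homoskedastic additive
noise (sd 10% of the gene's mean level) because it checks the
calibration of the OLS-based t test under its own error model; under
multiplicative noise the test is mildly anticonservative (~7% at nominal
5%), which is a robustness observation, not a calibration defect.

Two limitations surfaced by the validation are worth stating plainly:

* **StARS errs dense.** Its guarantee is that the selected graph
  *contains* the true edge set with high probability, not that precision
  is high. On a chain-structured precision matrix (p = 30, n = 500) the
  selected graph keeps every true edge but carries stable weak false
  edges, putting edge F1 near 0.7 (0.64–0.71 across data seeds in our
  experiments). Users wanting sparser networks should lower the
  instability threshold or report the strong-edge subset.
* **Covariate nodes under-adjust near-deterministic confounding.** The
  L1 penalty shrinks gene–proportion edges, so when a gene's expression
  is an almost noiseless function of composition, a residual gene–gene
  edge of order λ survives conditioning. The confounding demonstration
  therefore uses intrinsic expression noise comparable to real biological
  variability (lognormal sd 0.4), where suppression is essentially
  complete; with sd an order of magnitude smaller it is not.

# Numerical choices and degenerate inputs

* Constrained solvers: active-set with KKT tolerance 1e-10; simplex
  columns renormalized exactly at return.
* `k = 1` deconvolution returns the per-probe mean and unit proportions;
  `k = 1` stability is 1 by construction.
* Rank-deficient proportions (a cell type absent from all samples)
  yield NA expression columns with a warning rather than an error.
* Zero pooled SE in the t test: equal means give `t = 0, p = 1`; unequal
  means are flagged degenerate with a `p = 0` sentinel and a warning.
* Probe–covariate filtering: BH adjustment is applied per covariate (the
  tests are fit per covariate model, so the multiplicity is
  per-covariate); samples missing a covariate are dropped from that
  covariate's test only; constant covariates are skipped with a warning.
* The "three quartiles" of ranked-sample comparisons are implemented as
  terciles (three equal thirds), which is what splitting into three
  groups means.
* Log2 pseudocount 1 in the network stage; variables with zero variance
  are dropped with a warning.

# Session info

```{r}
sessionInfo()
```
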