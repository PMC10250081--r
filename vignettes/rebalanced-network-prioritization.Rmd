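---
title: "Rebalanced multi-omics network propagation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rebalanced multi-omics network propagation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moprio)
```

## The problem

Curated interaction databases give us one *general* network over two omics
types: gene–gene (g–g) functional interactions, metabolite–metabolite
(m–m) interactions, and gene–metabolite (g–m) cross-links, all scored on a
common 0–999 confidence scale. A disease study measures expression and
metabolite abundance on cases and controls and asks: which genes *and*
metabolites are associated with the disease? Propagating per-feature
evidence over the network is the standard answer, but the network is
severely imbalanced — tens of thousands of genes against a few hundred
metabolites — so g–g edges dominate any walk and the m–m and g–m blocks,
where much of the cross-omics signal lives, are effectively silenced.

`moprio` addresses this with three steps:

1. **Rebalance.** Multiply the g–g block by $\lambda_g$ and the m–m block
   by $\lambda_m$, leaving g–m untouched:
   $\tilde S_0 = \begin{bmatrix} \lambda_g S_g & S_{gm} \\ S_{gm}^T &
   \lambda_m S_m \end{bmatrix}$. With $\lambda_g < 1 < \lambda_m$ the
   within-omics blocks contribute comparably to the cross-omics block. The
   disease similarity matrix $E$ (absolute pairwise Pearson correlations
   of the omics profiles, zero diagonal) is rebalanced with the same
   weights, since it has the same shape and the same imbalance.
2. **Enhance.** Column-normalize $\tilde E$ and iterate the random walk
   with restart $S_{t+1} = \alpha \tilde E S_t + (1-\alpha)\tilde S_0$
   from $S_0 = \tilde S_0$ until the entrywise L1 change falls below
   `tol`. The converged matrix is symmetrized ($ (S + S^T)/2 $), each
   block is sparsified to its strongest edges (top 5% of nonzero g–g
   edges, 30% m–m, 15% g–m by weight), and the result is
   column-normalized into the enhanced, disease-specific network $S_E$.
3. **Prioritize.** Two-sided p-values per feature (Welch t-test for a
   case/control design, paired t-test for paired samples, or any p-values
   supplied directly) are mapped to nonnegative scores
   $v_0 = \Phi^{-1}(1 - p/2)$ and diffused:
   $v_{t+1} = \beta S_E v_t + (1-\beta) v_0$. Features are ranked on one
   combined gene+metabolite list, descending by the converged $v$.

Both recursions are contractions for $\alpha, \beta < 1$ when the driving
matrix has column sums at most one, with closed-form fixed points
$(1-\alpha)(I - \alpha \tilde E)^{-1}\tilde S_0$ and
$(1-\beta)(I - \beta S_E)^{-1} v_0$; the package implements the iteration
(the production path) and the direct solve (an oracle for tests and a
fast path for small problems), selected by a `solver` flag.

### Variants

* `reweighted` — the full method.
* `reweighted_s0` — rebalances the general network only, not the
  similarity matrix.
* `enhanced` — $\lambda_g = \lambda_m = 1$: enhancement without
  rebalancing (the method reduces to a direct multi-omics extension of
  single-omics network-enhancement prioritization).
* `general` — no enhancement: diffusion on the column-normalized,
  denoised general network. All variants share the same denoising so that
  differences reflect rebalancing and enhancement, not sparsity.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_g` | 0.05 | g–g block multiplier; < 1 mutes the oversized gene block |
| `lambda_m` | 20 | m–m block multiplier; > 1 amplifies the small metabolite block |
| `alpha` | 0.75 | enhancement restart mixing; 0 disables enhancement |
| `beta` | 0.75 | diffusion restart mixing; 0 returns the raw scores |
| `tol` | 1e-6 | entrywise L1 convergence tolerance of both recursions |
| `max_iter` | 1000 | iteration cap; exceeding it raises an error |
| `keep_gg`, `keep_mm`, `keep_gm` | 0.05, 0.30, 0.15 | retained fraction of *nonzero* edges per block |

The `lambda` defaults suit a network of roughly 5000 genes and 60
metabolites; more imbalanced networks call for smaller `lambda_g` and
larger `lambda_m`, less imbalanced ones the opposite. The denoising
fractions mirror the sparsity of the three blocks in curated databases
(g–g and g–m mostly zero-weight, m–m denser).

## Numerical choices

* **Zero columns** stay zero after column normalization. An isolated
  feature should not receive a fabricated uniform connection to
  everything; the sub-stochastic result keeps both recursions contractive
  because $\alpha, \beta < 1$ bound the spectral radius away from one.
* **Denoising base.** The retained fraction is computed over the
  *nonzero* edges of a block. Most possible pairs carry weight zero, so a
  fraction of all pairs would make the percentages meaningless.
* **Tie-breaks.** Edges tied at the denoising cut are kept in (weight
  descending, row, column) order; ranking ties are broken by score, then
  genes before metabolites, then identifier — all deterministic across
  platforms.
* **Asymmetry after normalization.** Column scaling breaks the symmetry
  of the full matrix, so a normalized network stores its
  metabolite-to-gene block explicitly (`mg`); undirected weight scales
  enforce `mg = t(gm)`.
* **Diagonals** of the within-omics blocks are forced to zero on
  construction: these are interaction networks without self-edges, and a
  zero diagonal prevents trivial self-reinforcement during diffusion.
* **Sparse path.** When the driving matrix has a nonzero fraction below
  5%, the iterative solver multiplies through a `Matrix` sparse
  representation; dense and sparse paths agree to well below the
  convergence tolerance.
* **p = 0 inputs** are clamped to 1e-300 (score ≈ 37) with a warning —
  such features dominate $v_0$ and deserve the user's attention.

## The synthetic study generator

The simulation module generates everything a study needs, with defaults
describing a case/control cohort of 100 + 100 samples over 5000 genes
(175 true signals) and 60 metabolites (12 true signals). Cases have
signal means 6.15 (genes) and 0.15 (metabolites) against baselines of 6
and 0; standard deviations are 2 and 2.5; controls sit at baseline
everywhere. Correlations are block-constant: 0.25 between signal genes,
0.20 between noise genes, 0.225 across; 0.30 / 0.15 / 0.225 for
metabolites; and four canonical gene–metabolite quadruples
(`rho_gm_settings()`) spanning weak to very strong cross-omics coupling
of signals.

### Exact sampling through the block structure

A block-constant correlation matrix is "rank-4 plus diagonal":
$R = Z A Z^T + D$ with $Z$ the feature-to-block indicator, $A$ the
$4\times4$ matrix of block correlations and $D = \mathrm{diag}(1 -
\rho_{bb})$. Its spectrum splits into the eigenvalues of the reduced
matrix $K = S^{1/2} A S^{1/2} + \mathrm{diag}(1-\rho_{bb})$ ($S$ = block
sizes) plus the always-positive within-block values $1-\rho_{bb}$.
Positive-definiteness is therefore checked, and repaired, on a
$4\times4$ matrix, and sampling costs $O(n)$ per sample instead of a
full-size Cholesky: each sample is a shared 4-vector of block factors
plus block-centred idiosyncratic noise. The repair clips eigenvalues of
$K$ at $10^{-8}$ and rescales to unit diagonal; if any correlation must
move by more than 0.05 the configuration is rejected as statistically
infeasible rather than silently altered.

This matters scientifically: block-constant designs obey a hard
feasibility bound,
$\rho_{gm}^2 \le \left(\rho_{gg} + \tfrac{1-\rho_{gg}}{n_g}\right)
\left(\rho_{mm} + \tfrac{1-\rho_{mm}}{n_m}\right)$,
for the signal blocks. With 0.25/0.30 within-block signal correlations
the strongest admissible gene–metabolite signal correlation is about 0.30
at 175/12 signals and about 0.35 at the 20/6 signals used in the scaled
study — the 0.5 quadruple is *not* a valid correlation structure at
realistic block sizes, and the generator refuses it. Consequences for
evaluation are in "Limitations" below.

### The synthetic network

`simulate_network()` stands in for a database subsample: independent
edges per block (defaults 5% g–g, 20% m–m, 5% g–m dense, matching the
sparsity regime of curated networks), integer confidence weights in
[1, 999] skewed toward small values with a heavy right tail, and an
enrichment knob (default 3) multiplying the edge probability among
signal features and between signal genes and signal metabolites. The
default of 3 puts the interaction ratio scores of signal features in the
several-fold-above-average range seen for disease features in real
subsamples; `enrichment = 1` gives a fully exchangeable network for
calibration work. What the generator does *not* emulate: degree
heterogeneity beyond the signal/noise split, modular or scale-free
topology, correlated edge weights, and identifier-mapping noise —
passing tests on synthetic data therefore demonstrate correctness of the
machinery and directional behaviour of the method, not performance on
any particular real network.

### Replicated studies

`run_study()` draws a fresh network and omics profile per replicate
(per-replicate seeds are `master + 2r - 1` for the network and
`master + 2r` for the omics, so any replicate can be reproduced in
isolation), runs the general baseline, the unrebalanced enhancement
baseline, and the rebalanced method at each grid point, and tabulates
top-k true-signal recovery. The study driver defaults to the direct
solver — study instances are small and the iterative/direct agreement is
itself under test — while `prioritize()` defaults to the iterative
production path.

The test suite exercises the study at 500 genes (20 signals) and 30
metabolites (6 signals), 20 replicates, k = 100, with the 0.2
gene–metabolite setting; null calibration uses 150 genes / 20 metabolites
with a 10% signal fraction in both types over 50 replicates. These sizes
were chosen so the whole suite, including the study, completes in about a
minute while keeping standard errors small relative to the effects
checked.

## Design decisions on open points

* **Correlation type** for the similarity matrix: Pearson by default
  (a Spearman switch exists). Similarity is computed on all samples
  pooled, matching how such matrices are built from full cohorts; an
  option to restrict is deliberately out of scope.
* **Combined ranking** over genes and metabolites together is primary
  (that is the point of joint prioritization); per-type ranks are also
  emitted.
* **Welch** is the default two-sample test, the safer choice under
  unequal variances; the pooled-variance test is an option.
* **g–m IRS for metabolites** uses column totals of the gene×metabolite
  block, the natural transpose of the gene-side definition.
* **Features without evidence** (present in the network, absent from a
  supplied p-value vector) get $p = 1$, i.e. zero initial score; they can
  still rise through diffusion.

## Limitations

* The feasibility bound above means very strong cross-omics signal
  correlations cannot be combined with the stated within-omics ones in
  an exact multivariate-normal design. The regime in which rebalancing
  is expected to *hurt* metabolite recovery (gene–metabolite signal
  correlation well above the within-metabolite one) is thus unreachable
  by a valid covariance at these block sizes; at the strongest feasible
  contrast (0.35 vs 0.30) the rebalanced method still saturates
  metabolite recovery in the scaled study, and the corresponding
  degradation check in the test suite fails by construction. The
  machinery for the comparison is implemented and tested; the
  statistical regime is not attainable.
* Identifier mapping between databases is out of scope: inputs must be
  pre-mapped, and `harmonize()` reports what fails to match.
* Only two omics layers are supported; the block composition is generic
  but no three-layer interface is exposed.
* Networks are undirected; confidence scores are used as given, with no
  rescaling between databases.
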