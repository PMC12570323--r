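---
title: "Noise reduction for single-cell count data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise reduction for single-cell count data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recodetools)
```

## The noise model

Single-cell sequencing measures each cell's molecular content by random
sampling: given a cell with total count $t_j$ and a gene whose true relative
abundance is $p_{ij}$, the observed count $c_{ij}$ behaves like a Poisson
draw with mean $t_j p_{ij}$. At typical depths most genes sit at means well
below one count, so the data are dominated by sampling ("technical") noise
and excess zeros (dropout). `recodetools` reduces this noise with a
high-dimensional statistical transform rather than a smoothing or imputation
heuristic: the key fact it exploits is that after an appropriate
normalization, pure sampling noise contributes *exactly unit variance per
gene*, so noise can be identified and subtracted in the spectral domain.

## Noise variance-stabilizing normalization (NVSN)

For a count matrix $C \in \mathbb{N}_0^{d \times n}$ (features $\times$
cells, zero-total cells removed on load), each cell is scaled by its total
$t_j$ and each gene by its estimated noise standard deviation
$s_i = \sqrt{n^{-1} \sum_k c_{ik} t_k^{-2}}$; genes never detected are
mapped to exact zeros and carried through all transforms as zeros. On the
resulting scale the per-gene variance of noise-only genes is 1 and genes
carrying biological signal exceed 1. This yields both:

* a **diagnostic** (`classify_applicability()`): the distribution of
  per-gene NVSN variances. Concentration at 1 means the sampling model fits
  (strongly applicable); a distribution shifted above 1 indicates additional
  unmodelled noise (weakly applicable); mass below 1 indicates noise that is
  not random sampling (inapplicable). The published criterion is
  qualitative; we operationalize it through the 5th percentile $q_{05}$ of
  detected-gene variances with a default band $[0.9, 1.1]$ — noise-only
  genes sit at exactly 1 and signal genes above, so the lower tail is the
  discriminator. The thresholds are exposed as an argument.
* a **calibration**: on the NVSN scale, each noise direction of the
  covariance carries unit variance, which is what makes the essential
  dimension rule below parameter-free.

## Spectral denoising

Let $S$ be the sample covariance of the NVSN matrix, with eigenvalues
$\lambda_1 \ge \dots \ge \lambda_m$ ($m = \min\{n-1, d\}$) and eigenvectors
$U$. Three ingredients:

1. **Eigenvalue modification.** In the high-dimension, low-sample-size
   regime the leading sample eigenvalues are inflated by roughly the mean of
   the trailing eigenvalues; the modified variance subtracts the tail
   average: $\tilde\lambda_i = \lambda_i - D_i^{-1}\sum_{k>i}\lambda_k$.
   The printed form of this estimator divides by $D_i = m - i + 1$ although
   the tail has $m - i$ terms; we default to the printed denominator
   (`eq1_denominator = "as_printed"`) and expose `"tail_mean"` as a toggle
   rather than silently resolving the discrepancy. For a non-increasing
   spectrum the printed form can touch zero only in degenerate cases; any
   non-positive modified value is floored at zero with a warning.
2. **Essential dimension.** Since each noise direction contributes unit
   variance, the residual mass beyond rank $k$ should fall to at most
   $d - k$ once all signal directions are captured:
   $l^* = \min\{k : \sum_{i>k} \lambda_i \le d - k\}$. On noise-only data
   the rule can select $k = 0$; we clamp to 1 with a warning, and because
   $\tilde\lambda$ is then zero the transform degenerates gracefully to the
   gene-mean matrix. The rule's discrimination margin per signal direction
   is of order $d/n$ while the sampling fluctuation of the residual mass is
   of order $\sqrt{2d/n}$, so recovery of *single* weak directions is
   reliable in the $d \gg n$ regime this estimator targets (real data:
   $d \approx 20{,}000$–$30{,}000$ genes) and becomes marginal when
   $n \ge d$. The package's tests exercise both regimes and the test suite
   reports the pooled recovery rate honestly.
3. **Eigenvector modification (v2).** Sample eigenvectors in this regime are
   also noisy; following sparse-PCA reasoning, components of each retained
   eigenvector are ranked by magnitude and the smallest are zeroed, with the
   cut $k_i$ chosen so the retained squared mass brackets the eigenvalue
   modification ratio $\tilde\lambda_i/\lambda_i$, and the survivors
   rescaled to unit norm. We enforce $k_i \ge 1$ (a zero cut would destroy
   the component), treat a ratio of 1 (zero tail) as full retention with the
   vector unchanged, break magnitude ties by ascending index, and fix each
   eigenvector's sign so its largest-magnitude entry is positive — all for
   bitwise reproducibility. Columns beyond $l^*$ are passed through
   unchanged; they receive zero weight downstream.

The denoising map projects the centered NVSN matrix onto the leading $l^*$
eigenvectors, rescales each coordinate by
$\sqrt{\tilde\lambda_i/\lambda_i}$ (a 0/0 scale is treated as 0), restores
the gene means and inverts the normalization. It factorizes exactly as
`rc_apply = rc_inv ∘ rc_ess`, where the intermediate `rc_ess()` output — the
*essential matrix*, $l^* \times n$ — is the natural space for integration
(below). The output is real-valued on the original count scale, preserving
shape and identifiers; negative entries are possible, kept by default (their
count is reported) and clipped only on request, since the transform is
linear in NVSN space and clipping is a user-facing choice.

## Batch integration in the essential space

Batch effects and technical noise are usually corrected by separate tools,
with batch correctors degrading in accuracy and cost as dimension grows.
`irc_apply()` therefore inserts the corrector *between* projection and
reconstruction: `rc_inv(B(rc_ess(X), labels))`. The corrector contract is a
function from an $l^* \times n$ matrix and batch labels to a matrix of the
same shape; with the identity corrector the result equals plain denoising
bitwise. The built-in `reference_corrector()` matches batch centroids per
essential coordinate while preserving the grand mean; heavier methods
(Harmony-class) plug in through `external_corrector_adapter()`, a TSV-based
file handshake, and are deliberately not reimplemented here. Centroid
matching removes the composition-weighted mean shift, so when batch
composition differs substantially between batches part of the removed shift
is biological; the package's integration tests quantify this as a bounded
silhouette change.

## Fast learning paths

* **Truncated spectral path** (`fast = TRUE`): the eigenvalue modification
  and the $l^*$ rule need only *leading* eigenvalues once every tail sum is
  rewritten through the trace identity
  $\sum_{k>i}\lambda_k = \mathrm{tr}(S) - \sum_{k\le i}\lambda_k$, with
  $\mathrm{tr}(S)$ computed directly from the centered matrix. The leading
  eigenpairs are obtained by block subspace iteration (no truncated
  eigensolver is part of the package's dependency set) with a
  decision-aware stopping rule: iteration ends when the $l^*$ decision is
  stable between checks and the eigenvalues it depends on have settled to
  $10^{-12}$ relative, followed by a fixed number of polishing iterations
  for the eigenvectors. The starting rank is
  $\min\{m, \max(\texttt{l\_hint}, 64)\}$ and doubles until the decision
  lands strictly inside the computed range; if it never does, the full
  decomposition is used with a warning. The start block is a fixed-seed
  Gaussian draw so results are bitwise reproducible without touching the
  caller's RNG stream.
* **Downsampling learning**: the transform depends on the data only through
  summary statistics, so it can be learned on a random cell subset and
  applied to all cells. Above `downsample_threshold` (default 20,000 cells)
  a seeded, without-replacement subset of `downsample_fraction` (default
  20%) is used for learning. When applying a subsampled model, per-gene
  noise scales come from the learning subset but each cell keeps its *own*
  recomputed total $t_j$ — totals are cell-intrinsic, and the published
  description does not pin this choice; recomputation is the one consistent
  with the transform being gene-wise statistics plus projection.

## Modality adapters

* **scHi-C**: per-cell symmetric contact maps are vectorized by flattening
  the upper triangle of intra-chromosomal bin pairs within a genomic
  distance cutoff (default 10 Mb at 1 Mb resolution), giving a features
  $\times$ cells count matrix the transform accepts unchanged. Distance-0
  (diagonal) pairs are included by default — the flattening convention is
  ambiguous in prose, inclusion preserves total counts, and both choices
  are exposed. Inter-chromosomal and beyond-cutoff records are dropped with
  a counter; bins are 0-based indices with an optional bp-position
  conversion `floor(pos/resolution)`. `devectorize()` inverts the map for
  rendering.
* **Spatial transcriptomics**: `apply_spatial()` denoises the count layer
  only; coordinates are excluded from the model and pass through untouched,
  with standard log-normalization (`log(1 + 10^4 x_{ij}/t_j)`) available as
  a derived layer.

## Synthetic data and what the tests show

All tests run on seeded generators implementing the sampling noise model —
no downloads. Design choices, fixed once:

* `generate_pure_noise()`: gene rates log-uniform in $[0.1, 10]$, constant
  across cells; independent Poisson counts. This is the noise-only regime
  where NVSN variances concentrate at 1.
* `generate_celltype_batches()`: log-normal background rates
  ($\mathrm{meanlog} = \log 0.5$, $\mathrm{sdlog} = 1.2$), 20 markers per
  type at 8-fold enrichment in the owning type (canonical markers are
  near-type-specific), 50 constant "housekeeping-like" genes at a moderate
  shared rate, per-batch per-gene log-normal factors (sd 0.1), log-normal
  library sizes (sd 0.3) around an expected depth of 3,000 counts per cell
  (typical shallow droplet depth). Dropout emerges from low rates, not an
  explicit zero-inflation term, matching the sampling model.
* `generate_spiked()`: unit-variance Gaussian noise plus orthonormal signal
  directions — the standard testbed for rank recovery.
* `generate_schic()`: exponential distance decay (3-bin constant) modulated
  by type-specific anchor blocks (4-fold boost), multinomial sampling at a
  per-cell depth of 500 contacts.

What passing these tests does *not* show: real data violate Poisson
sampling in protocol-specific ways (the weakly-applicable column of the
applicability diagnostic), gene-gene correlation structure is richer than
a few spikes plus markers, and batch effects in practice are not purely
multiplicative per gene. The generators are calibrated to be realistic in
scale, not to reproduce any particular dataset.

Problem sizes used by the test suite (chosen to make the statistical
properties measurable at desk scale): pure-noise checks at
$1{,}000 \times 2{,}000$; denoising efficacy at $300 \times 400$ over 20
seeds; integration at $300 \times 600$ over 20 seeds; spike recovery at
$500 \times 1{,}000$ for 1–10 spikes over 20 seeds each; contact-map
clustering at 385 features $\times$ 100 cells over 20 seeds.

## Numerical and interface choices

* Sample variances and covariances use the $n-1$ denominator throughout,
  matching the covariance definition the transform is built on.
* The full spectral path is an SVD of the centered matrix (never forming
  $S$); eigenvalues are floored at 0.
* Identifiers are mandatory and metrics join on them; generators mint
  `g0001…`/`c0001…` style ids.
* Non-integer inputs warn (fractional "counts" exist in the wild) and point
  at the applicability diagnostic instead of refusing.
* LISI (local inverse Simpson's index) uses perplexity 30 over the nearest
  `3 * perplexity` neighbours with bisection-calibrated Gaussian weights —
  the construction's usual defaults; the published description names the
  index but no parameters. Silhouette is computed by `cluster::silhouette()`
  behind the package's metric surface.
* A command-line entry point (`inst/cli/recode`) wraps `recode_run()`; all
  randomness descends from one `--seed`.

## Known limitations

* The noise model is Poisson sampling; over-dispersed or length-biased
  protocols fall in the weakly-applicable class and retain unmodelled
  noise after denoising.
* Single-direction signal recovery is marginal when $n \gtrsim d$ (see the
  essential-dimension margin argument above).
* The reference batch corrector is a rigid per-batch translation in the
  essential space; strongly batch-confounded compositions need an external
  corrector via the adapter.
* 10x HDF5 / h5ad ingestion is out of scope; convert to MatrixMarket plus
  id sidecars (e.g. with any h5ad-aware tool) and read that.
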