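# recodetools

Noise reduction for high-dimensional single-cell count data — scRNA-seq,
scATAC-seq, single-cell Hi-C contact maps and spatial transcriptomics — for
anyone whose downstream analysis (clustering, marker detection, integration)
is limited by dropout and sampling noise rather than by biology.

## The method

Sequencing a cell is random sampling: a gene with relative abundance
$p_{ij}$ in a cell with total count $t_j$ yields a count
$c_{ij} \sim \mathrm{Pois}(t_j p_{ij})$. **Noise variance-stabilizing
normalization (NVSN)** scales each cell by $t_j$ and each gene by its
estimated noise standard deviation
$s_i = \sqrt{n^{-1}\sum_k c_{ik} t_k^{-2}}$, after which pure sampling
noise has per-gene variance exactly 1. The denoising transform then works
on the spectrum of the NVSN covariance $S$:

* modified PC variances
  $\tilde\lambda_i = \lambda_i - \frac{1}{m-i+1}\sum_{k=i+1}^{m}\lambda_k$
  ($m = \min\{n-1, d\}$) correct the high-dimensional inflation of sample
  eigenvalues;
* the **essential dimension**
  $l^* = \min\{k : \sum_{i>k}\lambda_i \le d-k\}$ is the smallest rank at
  which the residual eigenvalue mass is at or below its unit-variance
  noise expectation;
* the transform projects the centered NVSN matrix onto the leading $l^*$
  eigenvectors, rescales coordinate $i$ by
  $\sqrt{\tilde\lambda_i/\lambda_i}$, restores the gene means and inverts
  the normalization — returning a real-valued matrix on the original count
  scale with the input's shape and identifiers. A v2 variant additionally
  sparsifies the retained eigenvectors (sparse-PCA style, calibrated by
  $\tilde\lambda_i/\lambda_i$).

The transform factorizes as `rc_apply = rc_inv ∘ rc_ess`, and batch
integration (`irc_apply`) inserts any batch corrector between the two — in
the $l^*$-dimensional essential space, never in gene space, so correction
cost and accuracy do not degrade with feature dimension. Fast learning is
available through a truncated spectral path (trace identity + subspace
iteration) and seeded downsampling learning (default: learn from 20% of
cells when a dataset exceeds 20,000 cells).

A built-in diagnostic, `classify_applicability()`, checks whether the
sampling noise model fits a dataset before you trust the output
(strongly/weakly applicable or inapplicable, from the distribution of
per-gene NVSN variances).

## Worked example

```r
library(recodetools)

# a synthetic dataset: 300 genes x 600 cells, 3 cell types, 2 batches,
# Poisson sampling noise, expected depth 3,000 counts/cell
sim <- generate_celltype_batches(300, 600, seed = 1)

classify_applicability(sim$counts)$class
#> [1] "strongly_applicable"

model <- recode_fit(sim$counts)
model
#> recode_model (original): 300 features, learned from 600 cells, l* = 4

denoised <- rc_apply(model, sim$counts)
attr(denoised, "n_negative")     # negative entries (kept, reported)
#> [1] 30

# specificity: housekeeping-like genes shrink, marker variation survives
vr <- variance_ratio(log_normalize(pmax(denoised, 0)),
                     log_normalize(as_dense(sim$counts)))
median(vr[sim$truth$constant_genes])   #> 0.042
median(vr[sim$truth$marker_genes])     #> 0.759

# batch integration in the essential space
integrated <- irc_apply(model, sim$counts, sim$truth$batches)
```

The model found an essential dimension of 4 (3 cell types + 1 batch
direction). After denoising, the median variance ratio of
housekeeping-like genes drops to 0.04 (their scatter was nearly all
sampling noise) while markers keep 76% of their variance (their scatter is
mostly biology). In this run, the mean per-cell-type cross-batch relative
error of gene means falls from 0.056 after denoising alone to 0.026 after
essential-space batch correction.

For the scHi-C path, build a `build_scheme()` for your chromosomes, feed
per-cell contact lists to `vectorize_contacts()`, denoise the resulting
matrix like any other, and map vectors back to symmetric maps with
`devectorize()`. For spatial data, `apply_spatial()` denoises counts while
leaving coordinates untouched.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the noise model,
every tunable parameter with its default and rationale, the synthetic-data
generators and the limits of what desk-scale tests demonstrate, numerical
edge-case handling, and known limitations.
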