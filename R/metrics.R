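#' Per-gene dropout rate
#'
#' Percentage of zero counts per gene across cells.
#'
#' @param c a [count_matrix()] or matrix
#' @return named numeric vector in [0, 100]
#' @export
dropout_rate <- function(c) {
  v <- if (inherits(c, "count_matrix")) c$values else c
  r <- 100 * (if (inherits(v, "Matrix")) Matrix::rowSums(v == 0) else
    rowSums(v == 0)) / ncol(v)
  stats::setNames(as.numeric(r), rownames(v))
}

#' Cross-batch relative error of gene means
#'
#' For gene i with mean expression \eqn{\bar x_i^{b}} in batch b,
#' \deqn{RE(i) = |\bar x_i^{b_1} - \bar x_i^{b_2}| /
#'   \max\{\bar x_i^{b_1}, \bar x_i^{b_2}\},}
#' assessed within one cell type at a time. Values lie in [0, 1] for
#' non-negative data; genes with both means zero return `NA` (undefined).
#'
#' @param values genes x cells matrix (typically log-normalized)
#' @param batch_labels batch per cell
#' @param celltype_labels optional cell-type per cell; when given, only cells
#'   of `celltype` enter the means
#' @param genes gene indices or names (default all)
#' @param batches the two batch labels to compare (default the first two)
#' @param celltype the cell type to restrict to (required with
#'   `celltype_labels`)
#' @return named numeric vector of RE values
#' @export
relative_error <- function(values, batch_labels, celltype_labels = NULL,
                           genes = NULL, batches = NULL, celltype = NULL) {
  if (length(batch_labels) != ncol(values))
    stop("batch label length does not match number of cells")
  keep <- rep(TRUE, ncol(values))
  if (!is.null(celltype_labels)) {
    if (is.null(celltype)) stop("celltype required with celltype_labels")
    keep <- celltype_labels == celltype
    if (!any(keep)) stop("empty group: no cells of cell type '", celltype, "'")
  }
  batches <- batches %||% utils::head(unique(batch_labels[keep]), 2L)
  if (length(batches) != 2L) stop("need exactly two batches to compare")
  g1 <- keep & batch_labels == batches[1]
  g2 <- keep & batch_labels == batches[2]
  if (!any(g1) || !any(g2)) stop("empty batch group within the cell type")
  if (is.null(genes)) genes <- seq_len(nrow(values))
  m1 <- rowMeans(values[genes, g1, drop = FALSE])
  m2 <- rowMeans(values[genes, g2, drop = FALSE])
  hi <- pmax(m1, m2)
  re <- ifelse(hi == 0, NA_real_, abs(m1 - m2) / hi)
  stats::setNames(re, rownames(values)[genes] %||% as.character(genes))
}

#' Welch's t statistic for a target-vs-rest contrast
#'
#' \deqn{t = (\bar X_t - \bar X_o) /
#'   \sqrt{\mathrm{var}(X_t)/n_t + \mathrm{var}(X_o)/n_o}}
#' with n-1 sample variances; used to score the spatial specificity of a
#' marker gene between target and non-target cell regions. Returns `NA`
#' (documented undefined marker, not an error) when both variances are zero.
#'
#' @param x_target,x_other numeric vectors, each of length >= 2
#' @return signed t value
#' @examples
#' welch_t(c(3, 4, 4, 5), c(1, 2, 2, 3))
#' @export
welch_t <- function(x_target, x_other) {
  if (length(x_target) < 2L || length(x_other) < 2L)
    stop("each group needs at least two observations")
  se2 <- stats::var(x_target) / length(x_target) +
    stats::var(x_other) / length(x_other)
  if (se2 == 0) return(NA_real_)
  (mean(x_target) - mean(x_other)) / sqrt(se2)
}

#' Silhouette scores for a labelled embedding
#'
#' Standard silhouette \eqn{s = (b - a)/\max(a, b)} with Euclidean distance,
#' contrasting mean intra-cluster distance a with the nearest other cluster's
#' mean distance b; singleton clusters score 0. Values lie in [-1, 1]; a high
#' mean indicates well-separated clusters.
#'
#' @param x cells x k coordinate matrix, or a `dist` object
#' @param labels cluster label per cell (>= 2 distinct)
#' @return list with `scores` (per point) and `mean`
#' @export
silhouette_score <- function(x, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least two clusters")
  d <- if (inherits(x, "dist")) x else stats::dist(x)
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  scores <- sil[, "sil_width"]
  list(scores = scores, mean = mean(scores))
}

#' Per-gene variance ratio between processed and raw data
#'
#' `var(processed_i) / var(raw_i)` per gene, the specificity check for
#' denoising: constant ("housekeeping-like") genes should shrink (ratio < 1)
#' while marker-gene variation should be preserved (ratio near 1). Both
#' matrices are expected log-normalized upstream. Genes with zero raw
#' variance return `NA`.
#'
#' @param processed,raw matrices of identical shape
#' @param gene_set optional gene indices or names to restrict to
#' @return named numeric vector of ratios
#' @export
variance_ratio <- function(processed, raw, gene_set = NULL) {
  if (!all(dim(processed) == dim(raw))) stop("shape mismatch")
  if (is.null(gene_set)) gene_set <- seq_len(nrow(raw))
  vp <- apply(processed[gene_set, , drop = FALSE], 1L, stats::var)
  vr <- apply(raw[gene_set, , drop = FALSE], 1L, stats::var)
  stats::setNames(ifelse(vr == 0, NA_real_, vp / vr),
                  rownames(raw)[gene_set] %||% as.character(gene_set))
}
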