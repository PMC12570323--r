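#' Fit the denoising transform
#'
#' Learns the complete transformation from a count matrix: the NVSN scale, and
#' the spectral model (eigenstructure, modified eigenvalues, essential
#' dimension, and for `variant = "v2"` the sparse-modified eigenvectors) of
#' the NVSN matrix. When the dataset exceeds `config$downsample_threshold`
#' cells and `config$downsample_fraction < 1`, learning uses a seeded,
#' uniformly random, without-replacement cell subset of size
#' `ceiling(fraction * n)` (downsampling learning); the fitted model is then
#' applied to the full matrix, each cell keeping its own recomputed total.
#'
#' @param c a [count_matrix()]
#' @param config a [recode_config()]
#' @return an object of class `recode_model`: `nvsn`, `spectral`, `variant`,
#'   `fit_cells` (ids used for learning), `config`
#' @examples
#' sim <- generate_pure_noise(50, 80, seed = 1)
#' model <- recode_fit(sim$counts)
#' model
#' @export
recode_fit <- function(c, config = recode_config()) {
  c <- count_matrix(c, warn_nonint = FALSE)
  n <- ncol(c$values)
  fit_idx <- seq_len(n)
  if (n > config$downsample_threshold && config$downsample_fraction < 1) {
    n_sub <- ceiling(config$downsample_fraction * n)
    if (n_sub < 10L) stop("downsampled learning subset has fewer than 10 cells")
    fit_idx <- withr::with_seed(config$seed, sort(sample.int(n, n_sub)))
  }
  c_fit <- if (length(fit_idx) < n)
    count_matrix(c$values[, fit_idx, drop = FALSE], warn_nonint = FALSE)
  else c
  nvsn <- fit_nvsn(c_fit)
  y <- nvsn_forward(nvsn, c_fit)
  spectral <- eigendecompose(y, fast = config$fast,
                             variant = config$variant,
                             denominator = config$eq1_denominator)
  structure(list(nvsn = nvsn, spectral = spectral, variant = config$variant,
                 fit_cells = c$cell_ids[fit_idx], config = config,
                 feature_ids = c$feature_ids),
            class = "recode_model")
}

#' @export
print.recode_model <- function(x, ...) {
  cat(sprintf(
    "recode_model (%s%s): %d features, learned from %d cells, l* = %d\n",
    x$variant, if (x$spectral$fast) ", truncated" else "",
    x$nvsn$d, length(x$fit_cells), x$spectral$essential_dim))
  invisible(x)
}

# Projection pieces shared by rc_ess / rc_inv: the leading l* columns of the
# (possibly modified) eigenvector matrix and the lambda scaling factors.
proj_parts <- function(model) {
  sp <- model$spectral
  l <- sp$essential_dim
  V <- if (model$variant == "v2") sp$modified_eigenvectors else sp$eigenvectors
  V <- V[, seq_len(min(l, ncol(V))), drop = FALSE]
  lam <- sp$eigenvalues[seq_len(ncol(V))]
  lam_mod <- sp$modified_eigenvalues[seq_len(ncol(V))]
  scale <- ifelse(lam > 0, sqrt(lam_mod / lam), 0)   # 0/0 treated as 0
  list(V = V, scale = scale, l = ncol(V))
}

input_totals <- function(model, x) {
  if (inherits(x, "count_matrix") || min(x) >= 0) {
    tj <- col_totals(if (inherits(x, "count_matrix")) x$values else x)
    if (any(tj <= 0)) stop("input contains zero-total cells")
    tj
  } else {
    stop("input matrix must be non-negative counts")
  }
}

#' Project into the essential space
#'
#' Computes the essential matrix
#' \eqn{\tilde\Lambda^{1/2}\Lambda^{-1/2} V^T [F_C(X) - \bar{F_C(C)}]}
#' where \eqn{V} is the leading-l* eigenvector block (modified under v2) and
#' the column means are the fitted NVSN-space gene means. Rows are the l*
#' essential coordinates; denoising amounts to reconstructing from these.
#'
#' @param model a [recode_fit()] model
#' @param x a [count_matrix()] or non-negative matrix with `model$nvsn$d` rows
#' @param cell_totals optional explicit per-cell totals \eqn{t_j}; by default
#'   each cell's own column total is used
#' @return an object of class `essential_matrix`: `values` (l* x n),
#'   `cell_ids`, `l`
#' @export
rc_ess <- function(model, x, cell_totals = NULL) {
  xm <- if (inherits(x, "count_matrix")) x$values else x
  if (nrow(xm) != model$nvsn$d)
    stop("feature mismatch: input has ", nrow(xm), " rows, model expects ",
         model$nvsn$d)
  tj <- cell_totals %||% input_totals(model, x)
  y <- nvsn_forward(model$nvsn, as_dense(xm), cell_totals = tj)
  p <- proj_parts(model)
  e <- (p$scale * t(p$V)) %*% (y - model$spectral$gene_means)
  structure(list(values = unname(e),
                 cell_ids = colnames(xm) %||% mint_ids("c", ncol(xm)),
                 cell_totals = tj, l = p$l),
            class = "essential_matrix")
}

#' Reconstruct from the essential space
#'
#' Computes \eqn{F_C^{-1}[V Y + \bar{F_C(C)}]}: lifts essential coordinates
#' back through the eigenvector block, restores the NVSN-space gene means,
#' and inverts the normalization using each cell's own total. Negative
#' entries are kept unless the model's config sets `clip_negative` (their
#' count is reported as attribute `n_negative` either way).
#'
#' @param model a [recode_fit()] model
#' @param e an [rc_ess()] result (or bare l* x n matrix plus `cell_totals`)
#' @param cell_totals required when `e` is a bare matrix
#' @return d x n denoised matrix on the original count scale
#' @export
rc_inv <- function(model, e, cell_totals = NULL) {
  if (inherits(e, "essential_matrix")) {
    values <- e$values; tj <- e$cell_totals; cid <- e$cell_ids
  } else {
    values <- e; tj <- cell_totals; cid <- colnames(e)
    if (is.null(tj)) stop("cell_totals required for a bare essential matrix")
  }
  p <- proj_parts(model)
  if (nrow(values) != p$l)
    stop("essential matrix has ", nrow(values), " rows, model expects ", p$l)
  y <- p$V %*% values + model$spectral$gene_means
  out <- nvsn_inverse(model$nvsn, y, cell_totals = tj)
  n_neg <- sum(out < 0)
  if (model$config$clip_negative) out[out < 0] <- 0
  dimnames(out) <- list(model$feature_ids, cid)
  attr(out, "n_negative") <- n_neg
  out
}

#' Apply the full denoising transform
#'
#' The composition `rc_inv(model, rc_ess(model, x))`: maps counts to the NVSN
#' scale, projects onto the essential subspace with modified-eigenvalue
#' shrinkage (v2 additionally uses modified eigenvectors), reconstructs, and
#' inverts the normalization. The output is real-valued, on the original
#' count scale, with the input's shape and feature/cell identifiers.
#'
#' @param model a [recode_fit()] model
#' @param x a [count_matrix()] or non-negative matrix with matching features
#' @return d x n denoised numeric matrix (attribute `n_negative` reports the
#'   count of negative entries before any clipping)
#' @examples
#' sim <- generate_pure_noise(50, 80, seed = 1)
#' model <- recode_fit(sim$counts)
#' denoised <- rc_apply(model, sim$counts)
#' @export
rc_apply <- function(model, x) {
  rc_inv(model, rc_ess(model, x))
}

#' One-call denoising
#'
#' Convenience wrapper: fit on `c` (honouring downsampling learning) and apply
#' to `c` itself.
#'
#' @inheritParams recode_fit
#' @return denoised matrix with attribute `model`
#' @export
recode <- function(c, config = recode_config()) {
  c <- count_matrix(c, warn_nonint = FALSE)
  model <- recode_fit(c, config)
  out <- rc_apply(model, c)
  attr(out, "model") <- model
  out
}
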