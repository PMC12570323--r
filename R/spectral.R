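#' Modify PC variances by tail-average subtraction
#'
#' In the high-dimension, low-sample-size regime the leading sample
#' eigenvalues are inflated by roughly the average of the trailing
#' eigenvalues. The modified variance subtracts that tail average:
#' \deqn{\tilde\lambda_i = \lambda_i - D_i^{-1} \sum_{k=i+1}^{m} \lambda_k,
#'   \quad i \le l,}
#' and 0 for \eqn{i > l}, with \eqn{m = \min\{n-1, d\}}. The printed estimator
#' divides by \eqn{D_i = m - i + 1} (`as_printed`, the default); the tail has
#' \eqn{m - i} terms, so `tail_mean` (\eqn{D_i = m - i}) is provided as a
#' documented toggle. Any non-positive modified value with \eqn{i \le l} is
#' floored at 0 with a warning.
#'
#' @param lambda non-increasing, non-negative eigenvalue vector
#' @param m number of eigenvalues retained, \eqn{\min\{n-1, d\}}; `lambda` is
#'   padded with zeros or truncated to this length
#' @param l essential dimension, `1 <= l <= m`
#' @param denominator `"as_printed"` or `"tail_mean"`
#' @return numeric vector of length `m`
#' @examples
#' modify_eigenvalues(c(5, 1, 0.9, 0.1), m = 4, l = 1)   # 4.5, 0, 0, 0
#' @export
modify_eigenvalues <- function(lambda, m = length(lambda), l,
                               denominator = c("as_printed", "tail_mean")) {
  denominator <- match.arg(denominator)
  if (any(diff(lambda) > 1e-8 * max(abs(lambda), 1)))
    stop("eigenvalues must be non-increasing")
  if (l < 1L || l > m) stop("essential dimension l must satisfy 1 <= l <= m")
  lambda <- c(lambda, numeric(m))[seq_len(m)]
  tail_sums <- rev(cumsum(rev(c(lambda[-1], 0))))   # tail_sums[i] = sum_{k>i}
  D <- if (denominator == "as_printed") m - seq_len(m) + 1 else
    pmax(m - seq_len(m), 1)
  lt <- lambda - tail_sums / D
  lt[seq_len(m) > l] <- 0
  if (any(lt[seq_len(l)] <= 0 & lambda[seq_len(l)] > 0)) {
    warning("non-positive modified eigenvalue(s) floored at 0")
  }
  lt[lt < 0] <- 0
  lt
}

#' Select the essential dimension l*
#'
#' The essential dimension is the smallest rank at which the residual
#' eigenvalue mass is at or below its noise expectation: on the NVSN scale
#' each noise direction carries unit variance, so
#' \deqn{l^* = \min\{k : \textstyle\sum_{i=k+1}^{d} \lambda_i \le d - k\},}
#' with \eqn{\lambda_i = 0} for \eqn{i > m}. A noise-only spectrum can yield
#' \eqn{k = 0}; the result is then clamped to 1 with a warning and the
#' downstream transform degenerates towards the mean matrix.
#'
#' @param lambda eigenvalue vector (length m, zero-padded internally)
#' @param d number of features
#' @return integer l* >= 1
#' @examples
#' essential_dimension(c(5, 1, 0.9, 0.1), d = 4)  # 1
#' @export
essential_dimension <- function(lambda, d) {
  total <- sum(lambda)
  lead <- cumsum(c(0, lambda))            # lead[k+1] = sum_{i<=k}
  k_max <- length(lambda)
  for (k in 0:k_max) {
    if (total - lead[k + 1] <= d - k) {
      if (k == 0L) {
        warning("degenerate essential dimension: rule selects 0, clamped to 1")
        return(1L)
      }
      return(as.integer(k))
    }
  }
  # residual mass above noise even at full rank; keep every component
  as.integer(k_max)
}

#' Sparse modification of the leading eigenvectors
#'
#' For each retained component \eqn{i \le l^*}, components of the eigenvector
#' are ranked by decreasing magnitude and the smallest are zeroed: the cut
#' \eqn{k_i} is the largest size whose cumulative squared mass stays below
#' the eigenvalue-modification ratio \eqn{\tilde\lambda_i/\lambda_i}
#' (enforced \eqn{k_i \ge 1}), and the retained components are rescaled to
#' unit norm. Columns beyond `l_star`, and columns with
#' \eqn{\tilde\lambda_i = 0}, are passed through unchanged (they receive zero
#' weight downstream). Ties in magnitude break by ascending index; the
#' ordering is stable.
#'
#' @param U d x m orthonormal eigenvector matrix
#' @param lambda,lambda_mod eigenvalues and modified eigenvalues (length m)
#' @param l_star essential dimension
#' @return d x m matrix with modified leading columns, unit-norm each
#' @export
modify_eigenvectors <- function(U, lambda, lambda_mod, l_star) {
  U_mod <- U
  for (i in seq_len(min(l_star, ncol(U)))) {
    if (lambda_mod[i] <= 0 || lambda[i] <= 0) next
    ratio <- lambda_mod[i] / lambda[i]
    if (!is.finite(ratio)) stop("non-finite eigenvalue-modification ratio")
    if (ratio >= 1 - 1e-12) next   # zero tail: full retention, unchanged
    u <- U[, i]
    ord <- order(-abs(u), seq_along(u))     # stable: ties by ascending index
    cum <- cumsum(u[ord]^2)
    k_i <- sum(cum < ratio)                 # largest k with cum[k] < ratio
    k_i <- max(1L, k_i)
    keep <- ord[seq_len(k_i)]
    v <- numeric(length(u))
    v[keep] <- u[keep] / sqrt(cum[k_i])
    U_mod[, i] <- v
  }
  U_mod
}

# Fix eigenvector signs: each column's largest-magnitude entry positive.
fix_signs <- function(U) {
  if (ncol(U) == 0L) return(U)
  piv <- apply(abs(U), 2L, which.max)
  s <- sign(U[cbind(piv, seq_len(ncol(U)))])
  s[s == 0] <- 1
  sweep(U, 2L, s, "*")
}

# Leading r eigenpairs of Z Z^T / (n-1) by block subspace iteration on the
# centered matrix Z (d x n). Convergence is decision-aware: iteration stops
# once the essential-dimension decision k (obtained from the leading partial
# sums plus the trace identity) is stable between checks and the eigenvalues
# it depends on have settled; a few polishing iterations then tighten the
# eigenvectors. Returns NULL when the decision never lands strictly inside
# the computed range.
subspace_eigs <- function(Z, r, d, total_variance, tol = 1e-12,
                          max_iter = 300L, polish = 15L) {
  n <- ncol(Z)
  r_pad <- min(nrow(Z), n - 1L, r + 10L)
  # deterministic Gaussian start block: bitwise-reproducible results without
  # touching the caller's RNG stream
  omega <- withr::with_seed(723001L, matrix(stats::rnorm(n * r_pad), n, r_pad))
  Q <- qr.Q(qr(Z %*% omega))
  ev_old <- rep(Inf, r_pad)
  k_old <- -1L
  decide <- function(ev) {
    tail_k <- total_variance - cumsum(c(0, ev))   # at k = 0..length(ev)
    ok <- which(tail_k <= d - (0:length(ev)))
    if (length(ok)) min(ok) - 1L else NA_integer_
  }
  finish <- function(Q) {
    for (p in seq_len(polish)) Q <- qr.Q(qr(Z %*% crossprod(Z, Q)))
    sv <- svd(crossprod(Q, Z), nu = r_pad, nv = 0L)
    list(values = pmax(sv$d^2 / (n - 1), 0)[seq_len(min(r, r_pad))],
         vectors = (Q %*% sv$u)[, seq_len(min(r, r_pad)), drop = FALSE])
  }
  for (it in seq_len(max_iter)) {
    Q <- qr.Q(qr(Z %*% crossprod(Z, Q)))
    if (it %% 5L == 0L) {
      ev <- pmax(svd(crossprod(Q, Z), nu = 0L, nv = 0L)$d^2 / (n - 1), 0)
      k <- decide(ev)
      if (!is.na(k) && k < min(r, r_pad)) {
        lead <- seq_len(min(k + 3L, r_pad))
        settled <- max(abs(ev[lead] - ev_old[lead]) /
                         pmax(ev[lead], 1e-300)) < tol
        if (k == k_old && settled) {
          out <- finish(Q)
          out$khat <- decide(out$values)
          if (!is.na(out$khat) && out$khat < min(r, r_pad)) return(out)
        }
        k_old <- k
      }
      ev_old <- ev
    }
  }
  NULL
}

#' Eigendecompose the NVSN covariance
#'
#' Builds the spectral model of \eqn{S = (Y - YP)(Y - YP)^T/(n-1)}:
#' eigenvalues, eigenvectors, total variance (trace), the essential dimension
#' l*, the modified eigenvalues, and (for `variant = "v2"`) the modified
#' eigenvectors. The full path takes an SVD of the centered matrix. The fast
#' path computes only the leading `r` eigenpairs by converged block subspace
#' iteration and recovers every tail sum from the trace identity
#' \eqn{\sum_{k>i} \lambda_k = \mathrm{tr}(S) - \sum_{k \le i} \lambda_k},
#' so the eigenvalue modification and l* need only leading eigenvalues;
#' `r` starts at `min(m, max(l_hint, 64))` and doubles until l* is decided
#' inside the computed range, falling back to the full path (with a warning)
#' if it never is.
#'
#' @param y NVSN-scale matrix, d x n
#' @param fast use the truncated path
#' @param l_hint anticipated essential dimension (fast path starting rank)
#' @param variant `"original"` or `"v2"`
#' @param denominator see [modify_eigenvalues()]
#' @return an object of class `spectral_model`: `eigenvalues`,
#'   `modified_eigenvalues`, `eigenvectors`, `modified_eigenvectors`,
#'   `essential_dim`, `gene_means`, `total_variance`, `m`, `fast`
#' @export
eigendecompose <- function(y, fast = FALSE, l_hint = 32L,
                           variant = c("original", "v2"),
                           denominator = c("as_printed", "tail_mean")) {
  variant <- match.arg(variant)
  denominator <- match.arg(denominator)
  y <- as_dense(y)
  if (anyNA(y) || any(!is.finite(y))) stop("matrix must be finite")
  d <- nrow(y); n <- ncol(y)
  gene_means <- rowMeans(y)
  Z <- y - gene_means
  m <- min(n - 1L, d)
  if (m < 1L) stop("need at least two cells")
  total_variance <- sum(Z^2) / (n - 1)

  lam <- NULL; U <- NULL; used_fast <- FALSE
  if (fast) {
    r <- min(m, max(as.integer(l_hint), 64L))
    repeat {
      eg <- subspace_eigs(Z, r, d, total_variance)
      if (!is.null(eg)) {
        lam <- eg$values; U <- eg$vectors; used_fast <- TRUE
        break
      }
      if (r >= m) {
        warning("truncated rank reached m without deciding l*; ",
                "falling back to the full decomposition")
        break
      }
      r <- min(m, 2L * r)
    }
  }
  if (is.null(lam)) {
    sv <- svd(Z, nu = m, nv = 0L)
    lam <- (sv$d^2 / (n - 1))[seq_len(m)]
    lam <- pmax(lam, 0)
    U <- sv$u
  }
  U <- fix_signs(U)

  if (used_fast) {
    r <- length(lam)
    tail_k <- total_variance - cumsum(c(0, lam))
    ok <- which(tail_k <= d - (0:r))
    k <- min(ok) - 1L
    if (k == 0L) {
      warning("degenerate essential dimension: rule selects 0, clamped to 1")
      l_star <- 1L
    } else l_star <- as.integer(k)
    # Eq. 1 via trace identity on the leading block
    D <- if (denominator == "as_printed") m - seq_len(r) + 1 else
      pmax(m - seq_len(r), 1)
    lam_mod <- lam - (total_variance - cumsum(lam)) / D
    lam_mod[seq_len(r) > l_star] <- 0
    if (any(lam_mod[seq_len(l_star)] < 0)) {
      warning("non-positive modified eigenvalue(s) floored at 0")
      lam_mod[lam_mod < 0] <- 0
    }
  } else {
    l_star <- essential_dimension(lam, d)
    lam_mod <- modify_eigenvalues(lam, m = m, l = min(l_star, m),
                                  denominator = denominator)
  }

  U_mod <- if (variant == "v2")
    modify_eigenvectors(U, lam, lam_mod, min(l_star, ncol(U))) else U

  structure(list(eigenvalues = lam, modified_eigenvalues = lam_mod,
                 eigenvectors = U, modified_eigenvectors = U_mod,
                 essential_dim = as.integer(l_star), gene_means = gene_means,
                 total_variance = total_variance, m = m, d = d,
                 variant = variant, fast = used_fast),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf(
    "spectral_model: d = %d, m = %d, l* = %d, trace = %.4g (%s%s)\n",
    x$d, x$m, x$essential_dim, x$total_variance, x$variant,
    if (x$fast) ", truncated" else ""))
  invisible(x)
}

#' Save / load a spectral model as a flat-file bundle
#'
#' Writes the eigenstructure needed to reapply a fitted transform as plain
#' TSV files inside a directory: scalars, eigenvalues (raw and modified),
#' gene means, and the leading `l*` columns of the (modified) eigenvectors.
#'
#' @param model a `spectral_model`
#' @param dir directory to create
#' @export
write_spectral_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  w(data.frame(key = c("essential_dim", "total_variance", "m", "d", "variant"),
               value = c(model$essential_dim, model$total_variance, model$m,
                         model$d, model$variant)), "scalars.tsv")
  w(data.frame(eigenvalue = model$eigenvalues,
               modified = model$modified_eigenvalues), "eigenvalues.tsv")
  w(data.frame(gene_mean = model$gene_means), "gene_means.tsv")
  l <- model$essential_dim
  w(as.data.frame(model$eigenvectors[, seq_len(l), drop = FALSE]), "U.tsv")
  w(as.data.frame(model$modified_eigenvectors[, seq_len(l), drop = FALSE]),
    "U_mod.tsv")
  invisible(dir)
}
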