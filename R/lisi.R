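#' Local inverse Simpson's index (LISI)
#'
#' For each cell, Gaussian-kernel weights over its `3 * perplexity` nearest
#' neighbours are calibrated (by bisection on the kernel bandwidth) so their
#' entropy equals `log(perplexity)`; the per-label weight masses \eqn{p_l}
#' give the index \eqn{1/\sum_l p_l^2}. Values range from 1 (a single label
#' dominates every neighbourhood) to the number of distinct labels (perfect
#' local mixing). Computed on batch labels this measures integration (iLISI,
#' higher is better); on cell-type labels it measures conservation (cLISI,
#' near 1 is better). The cell itself is excluded from its neighbourhood.
#'
#' @param embedding cells x k coordinate matrix
#' @param labels label per cell
#' @param perplexity effective neighbourhood size (default 30)
#' @return numeric vector, one index per cell
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  labels <- as.integer(factor(as.character(labels)))
  if (length(labels) != n) stop("label length does not match embedding rows")
  k <- min(n - 1L, 3L * perplexity)
  if (n < 3L * perplexity)
    stop("need at least 3 * perplexity cells (", 3L * perplexity,
         "), got ", n)
  d2 <- as.matrix(stats::dist(embedding))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, -i])[seq_len(k)]
    idx <- seq_len(n)[-i][nb]
    p <- calibrate_gaussian(d2[i, idx], perplexity)
    mass <- rowsum(p, labels[idx])
    out[i] <- 1 / sum(mass^2)
  }
  out
}

# Bisection on beta so that the entropy of p ~ exp(-beta * d2) equals
# log(perplexity); degenerate (all-equal) distances fall back to equal
# weights with a warning.
calibrate_gaussian <- function(d2, perplexity, tol = 1e-5, max_iter = 64L) {
  if (max(d2) - min(d2) < .Machine$double.eps * max(d2, 1)) {
    warning("degenerate distances: equal-weight neighbourhood used")
    return(rep(1 / length(d2), length(d2)))
  }
  d2 <- d2 - min(d2)
  target <- log(perplexity)
  beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    h <- log(sw) + beta * sum(d2 * w) / sw
    if (abs(h - target) < tol) break
    if (h > target) { beta_lo <- beta
      beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
    } else { beta_hi <- beta
      beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
    }
  }
  w <- exp(-beta * d2)
  w / sum(w)
}
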