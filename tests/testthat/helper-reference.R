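# Independent reference implementations used as oracles. Deliberately naive:
# plain loops and full sorts, no code shared with the package.

# O(n^2) LISI reference: full distance matrix, per-cell bandwidth calibrated
# by explicit bisection to entropy log(perplexity) over the 3*perplexity
# nearest neighbours, inverse Simpson over label masses.
ref_lisi <- function(emb, labels, perplexity = 30) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  labs <- as.integer(factor(labels))
  k <- min(n - 1L, 3L * perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(emb) - emb[i, ])^2)
    ord <- setdiff(order(d2), i)[seq_len(k)]
    dd <- d2[ord] - min(d2[ord])
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:100) {
      w <- exp(-beta * dd)
      H <- log(sum(w)) + beta * sum(dd * w) / sum(w)
      if (abs(H - log(perplexity)) < 1e-7) break
      if (H > log(perplexity)) {
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + beta) / 2
      }
    }
    w <- exp(-beta * dd); w <- w / sum(w)
    p <- tapply(w, labs[ord], sum)
    out[i] <- 1 / sum(p^2)
  }
  out
}

# Brute-force feature count for a single chromosome: enumerate all pairs.
ref_feature_count <- function(L, D, include_diagonal = TRUE) {
  cnt <- 0L
  for (i in 0:(L - 1)) for (j in i:(L - 1)) {
    if (!include_diagonal && j == i) next
    if (j - i <= D) cnt <- cnt + 1L
  }
  cnt
}

# Tiny dense fixture with guaranteed positive cell totals.
make_counts <- function(d = 6, n = 8, seed = 42, lambda = 3) {
  withr::with_seed(seed, {
    v <- matrix(stats::rpois(d * n, lambda), d, n)
    v[1, ] <- v[1, ] + 1  # no zero-total cells
  })
  count_matrix(v)
}
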