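#' Simulate pure sampling noise (no biological signal)
#'
#' Gene rates are drawn log-uniformly in `[rate_low, rate_high]` and held
#' constant across cells; counts are independent Poisson draws. This is the
#' noise-only regime in which the NVSN variance of every detected gene
#' concentrates at 1 and the data are classified strongly applicable.
#'
#' @param d,n numbers of genes and cells
#' @param rate_low,rate_high rate range (defaults 0.1 and 10)
#' @param seed integer seed; generation is bit-reproducible
#' @return list with `counts` (a [count_matrix()]) and `truth` (rates,
#'   normalized `true_rates`, empty label sets)
#' @export
generate_pure_noise <- function(d, n, rate_low = 0.1, rate_high = 10,
                                seed = 0L) {
  stopifnot(d >= 1, n >= 1, rate_low > 0, rate_high >= rate_low)
  withr::with_seed(as.integer(seed), {
    rates <- exp(stats::runif(d, log(rate_low), log(rate_high)))
    values <- matrix(stats::rpois(d * n, rates), d, n)
  })
  counts <- count_matrix(values, feature_ids = mint_ids("g", d),
                         cell_ids = mint_ids("c", n), warn_nonint = FALSE)
  rates_kept <- rates   # rates per gene; columns identical
  true_rates <- matrix(rates_kept / sum(rates_kept), d, ncol(counts$values))
  list(counts = counts,
       truth = list(rates = rates_kept, true_rates = true_rates,
                    cell_types = NULL, batches = NULL,
                    marker_genes = integer(0), constant_genes = integer(0)))
}

#' Simulate cell types with batch effects under sampling noise
#'
#' Cell-type-specific rate profiles: background genes draw log-normal base
#' rates; each type owns `n_markers` marker genes whose rate is multiplied by
#' `effect_size` in that type; `n_constant` "housekeeping-like" genes share a
#' fixed moderate rate in every type. Batch effects are per-batch, per-gene
#' multiplicative log-normal factors of spread `batch_strength` (0 means all
#' factors are exactly 1). Library sizes are log-normal (sd 0.3 on the log
#' scale) and counts are Poisson of rate x batch factor x library size, so
#' dropout emerges from low rates rather than an explicit zero-inflation.
#'
#' @param d,n numbers of genes and cells
#' @param n_types,n_batches numbers of cell types and batches (cells assigned
#'   uniformly at random)
#' @param effect_size marker fold-change in the owning type (default 8,
#'   mirroring the near-type-specific expression of canonical markers)
#' @param batch_strength sd of the log-normal batch factors (default 0.1)
#' @param seed integer seed
#' @param n_markers markers per type (default 20)
#' @param n_constant housekeeping-like genes (default 50)
#' @param depth expected total counts per cell before the library-size draw
#'   (default 3000, a typical shallow droplet depth)
#' @return list with `counts` and `truth` (`true_rates` = expected
#'   size-normalized expression per cell including batch factors, columns
#'   summing to 1; `cell_types`; `batches`; `batch_factors`; `marker_genes`;
#'   `constant_genes`)
#' @export
generate_celltype_batches <- function(d, n, n_types = 3L, n_batches = 2L,
                                      effect_size = 8, batch_strength = 0.1,
                                      seed = 0L, n_markers = 20L,
                                      n_constant = 50L, depth = 3000) {
  stopifnot(d >= n_types * n_markers + n_constant, n >= 2 * n_types * n_batches)
  withr::with_seed(as.integer(seed), {
    marker_genes <- seq_len(n_types * n_markers)
    constant_genes <- n_types * n_markers + seq_len(n_constant)
    base <- stats::rlnorm(d, meanlog = log(0.5), sdlog = 1.2)
    base[marker_genes] <- 1
    base[constant_genes] <- 5
    profile <- matrix(base, d, n_types)          # gene x type relative rates
    for (t in seq_len(n_types)) {
      own <- (t - 1L) * n_markers + seq_len(n_markers)
      profile[own, t] <- profile[own, t] * effect_size
    }
    batch_factors <- matrix(
      if (batch_strength > 0)
        stats::rlnorm(d * n_batches, 0, batch_strength) else 1,
      d, n_batches)
    cell_types <- sample(rep_len(seq_len(n_types), n))
    batches <- sample(rep_len(seq_len(n_batches), n))
    lib <- stats::rlnorm(n, 0, 0.3)
    rate <- profile[, cell_types] * batch_factors[, batches]
    rate <- sweep(rate, 2L, depth * lib / colSums(rate), "*")
    values <- matrix(stats::rpois(d * n, rate), d, n)
  })
  counts <- count_matrix(values, feature_ids = mint_ids("g", d),
                         cell_ids = mint_ids("c", n), warn_nonint = FALSE)
  kept <- match(counts$cell_ids, mint_ids("c", n))
  rate <- rate[, kept, drop = FALSE]
  list(counts = counts,
       truth = list(true_rates = sweep(rate, 2L, colSums(rate), "/"),
                    cell_types = paste0("type", cell_types[kept]),
                    batches = paste0("batch", batches[kept]),
                    batch_factors = batch_factors,
                    marker_genes = marker_genes,
                    constant_genes = constant_genes))
}

#' Simulate a spiked covariance matrix on the stabilized (NVSN) scale
#'
#' Isotropic unit-variance Gaussian noise plus `length(spikes)` orthonormal
#' signal directions of the given strengths: the population covariance is
#' \eqn{I + \sum_s \theta_s u_s u_s^T} with trace \eqn{d + \sum_s \theta_s}.
#' The standard testbed for essential-dimension recovery.
#'
#' @param d,n dimensions
#' @param spikes numeric vector of signal strengths (may be empty)
#' @param seed integer seed
#' @return list with `values` (d x n matrix) and `truth` (`directions`,
#'   `strengths`, `scores`)
#' @export
generate_spiked <- function(d, n, spikes = c(10, 9, 8), seed = 0L) {
  s <- length(spikes)
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(d * n), d, n)
    if (s > 0) {
      U <- qr.Q(qr(matrix(stats::rnorm(d * s), d, s)))
      scores <- matrix(stats::rnorm(s * n), s, n)
      values <- noise + U %*% (sqrt(spikes) * scores)
    } else {
      U <- matrix(0, d, 0); scores <- matrix(0, 0, n)
      values <- noise
    }
  })
  list(values = values,
       truth = list(directions = U, strengths = spikes, scores = scores))
}

#' Simulate single-cell contact maps with cell-type structure
#'
#' Each cell type owns an in-band intensity template: an exponential
#' distance-decay baseline (`exp(-dist / decay)` in bins) modulated by
#' type-specific anchor blocks (random anchor bins whose pairs are boosted
#' `block_boost`-fold). Each cell draws `depth` contacts multinomially from
#' its type's template, so per-cell maps are sparse, noisy renderings of the
#' type pattern.
#'
#' @param n_cells number of cells
#' @param scheme a [build_scheme()] result
#' @param n_types number of cell types (default 2)
#' @param depth contacts per cell (default 500)
#' @param seed integer seed
#' @param decay distance-decay constant in bins (default 3)
#' @param block_boost anchor-pair intensity multiplier (default 4)
#' @return list with `cells` (contact data.frames for
#'   [vectorize_contacts()]), `truth` (`cell_types`, `templates` features x
#'   types)
#' @export
generate_schic <- function(n_cells, scheme, n_types = 2L, depth = 500L,
                           seed = 0L, decay = 3, block_boost = 4) {
  feat <- scheme$features
  dist_bins <- feat$bin_j - feat$bin_i
  withr::with_seed(as.integer(seed), {
    templates <- vapply(seq_len(n_types), function(t) {
      w <- exp(-dist_bins / decay)
      anchors <- unlist(lapply(names(scheme$n_bins), function(ch) {
        L <- scheme$n_bins[[ch]]
        paste(ch, sample.int(L, max(1L, L %/% 5L)) - 1L)
      }))
      hit <- paste(feat$chrom, feat$bin_i) %in% anchors |
        paste(feat$chrom, feat$bin_j) %in% anchors
      w[hit] <- w[hit] * block_boost
      w / sum(w)
    }, numeric(nrow(feat)))
    cell_types <- sample(rep_len(seq_len(n_types), n_cells))
    cells <- lapply(seq_len(n_cells), function(j) {
      cnt <- as.integer(stats::rmultinom(1L, depth, templates[, cell_types[j]]))
      nz <- cnt > 0
      data.frame(chrom = feat$chrom[nz], bin_i = feat$bin_i[nz],
                 bin_j = feat$bin_j[nz], count = cnt[nz])
    })
  })
  names(cells) <- mint_ids("c", n_cells)
  list(cells = cells,
       truth = list(cell_types = paste0("type", cell_types),
                    templates = templates))
}
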