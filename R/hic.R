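#' Build a contact-pair feature scheme
#'
#' Defines the bijection between intra-chromosomal bin pairs and flattened
#' feature indices: a cell's symmetric contact map is vectorized by flattening
#' the upper triangle, keeping pairs whose inter-bin distance is at most
#' `max_distance` base pairs. Feature order is deterministic: chromosomes in
#' the given order, then anchor bin ascending, then distance ascending. For a
#' chromosome of L bins with distance cutoff `D = max_distance/resolution`
#' bins (diagonal included, L > D) the feature count is
#' `L*(D+1) - D*(D+1)/2`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp (or a
#'   two-column data.frame: name, length)
#' @param resolution bin size in bp
#' @param max_distance maximum inter-bin distance in bp (default 10 Mb)
#' @param include_diagonal keep distance-0 (diagonal) pairs
#' @return an object of class `contact_scheme` with a feature table
#'   (`chrom`, `bin_i`, `bin_j`), `n_features`, bin counts, and parameters.
#'   Bin indices are 0-based.
#' @examples
#' sc <- build_scheme(c(chr1 = 5e6), resolution = 1e6, max_distance = 2e6)
#' sc$n_features  # 5 + 4 + 3 = 12
#' @export
build_scheme <- function(chrom_sizes, resolution = 1e6, max_distance = 1e7,
                         include_diagonal = TRUE) {
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- stats::setNames(chrom_sizes[[2]], chrom_sizes[[1]])
  stopifnot(resolution > 0, max_distance >= 0)
  n_bins <- ceiling(chrom_sizes / resolution)
  if (any(n_bins < 1L)) stop("zero-length chromosome: ",
                             paste(names(n_bins)[n_bins < 1L], collapse = ", "))
  D <- floor(max_distance / resolution)
  d_min <- if (include_diagonal) 0L else 1L
  if (D < d_min) stop("distance cutoff excludes every pair")
  feats <- do.call(rbind, lapply(names(n_bins), function(ch) {
    L <- n_bins[[ch]]
    bi <- rep(seq_len(L) - 1L, each = D - d_min + 1L)
    dist <- rep(d_min:D, times = L)
    keep <- bi + dist <= L - 1L & dist >= d_min
    data.frame(chrom = ch, bin_i = bi[keep], bin_j = (bi + dist)[keep],
               stringsAsFactors = FALSE)
  }))
  key <- paste(feats$chrom, feats$bin_i, feats$bin_j)
  structure(list(features = feats, n_features = nrow(feats),
                 index = stats::setNames(seq_len(nrow(feats)), key),
                 n_bins = n_bins, resolution = resolution,
                 max_distance = max_distance, D = D,
                 include_diagonal = include_diagonal),
            class = "contact_scheme")
}

#' @export
print.contact_scheme <- function(x, ...) {
  cat(sprintf(
    "contact_scheme: %d chromosome(s), %d bp bins, cutoff %d bins, %d features\n",
    length(x$n_bins), as.integer(x$resolution), x$D, x$n_features))
  invisible(x)
}

#' Map (chrom, bin_i, bin_j) pairs to feature indices
#'
#' Pairs are normalized to `bin_i <= bin_j`. Out-of-band pairs (beyond the
#' distance cutoff, excluded diagonal, or unknown chromosome) map to `NA`.
#'
#' @param scheme a [build_scheme()] result
#' @param chrom,bin_i,bin_j vectors describing pairs (0-based bins)
#' @return integer feature indices (NA when out of band)
#' @export
pair_to_index <- function(scheme, chrom, bin_i, bin_j) {
  lo <- pmin(bin_i, bin_j); hi <- pmax(bin_i, bin_j)
  unname(scheme$index[paste(chrom, lo, hi)])
}

#' Vectorize per-cell contact lists into a count matrix
#'
#' Each cell is a data.frame with columns `chrom`, `bin_i`, `bin_j`, `count`
#' (0-based bin indices; unordered pairs are normalized so `bin_i <= bin_j`).
#' Inter-chromosomal records and records beyond the distance cutoff are
#' dropped, with the dropped-record count reported; duplicates for one pair
#' are summed. Bin indices outside the chromosome are an error.
#'
#' @param cells named list of per-cell contact data.frames
#' @param scheme a [build_scheme()] result
#' @return a [count_matrix()] (features x cells) with attribute `n_dropped`
#' @export
vectorize_contacts <- function(cells, scheme) {
  if (is.null(names(cells))) names(cells) <- mint_ids("c", length(cells))
  values <- matrix(0, scheme$n_features, length(cells))
  dropped <- 0L
  for (j in seq_along(cells)) {
    rec <- cells[[j]]
    if (nrow(rec) == 0L) next
    known <- rec$chrom %in% names(scheme$n_bins)
    dropped <- dropped + sum(!known)      # inter-chromosomal/unknown contig
    rec <- rec[known, , drop = FALSE]
    if (nrow(rec) == 0L) next
    L <- scheme$n_bins[rec$chrom]
    if (any(rec$bin_i >= L | rec$bin_j >= L | rec$bin_i < 0 | rec$bin_j < 0))
      stop("bin index outside chromosome in cell ", names(cells)[j])
    idx <- pair_to_index(scheme, rec$chrom, rec$bin_i, rec$bin_j)
    dropped <- dropped + sum(is.na(idx))
    ok <- !is.na(idx)
    if (any(ok)) {
      agg <- rowsum(rec$count[ok], idx[ok])
      values[as.integer(rownames(agg)), j] <- agg[, 1]
    }
  }
  feat <- scheme$features
  out <- count_matrix(values,
                      feature_ids = sprintf("%s:%d-%d", feat$chrom,
                                            feat$bin_i, feat$bin_j),
                      cell_ids = names(cells), warn_nonint = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Rebuild symmetric per-chromosome contact maps from a feature vector
#'
#' Inverse of the flattening: every in-band entry is placed at (i, j) and
#' mirrored to (j, i); out-of-band entries are 0.
#'
#' @param values numeric vector of length `scheme$n_features` (one cell)
#' @param scheme a [build_scheme()] result
#' @return named list of symmetric L x L matrices, one per chromosome
#' @export
devectorize <- function(values, scheme) {
  if (length(values) != scheme$n_features)
    stop("vector length ", length(values), " does not match scheme feature ",
         "count ", scheme$n_features)
  feat <- scheme$features
  maps <- lapply(names(scheme$n_bins), function(ch) {
    L <- scheme$n_bins[[ch]]
    m <- matrix(0, L, L)
    sel <- feat$chrom == ch
    i <- feat$bin_i[sel] + 1L; j <- feat$bin_j[sel] + 1L
    m[cbind(i, j)] <- values[sel]
    m[cbind(j, i)] <- values[sel]
    m
  })
  stats::setNames(maps, names(scheme$n_bins))
}

#' Read per-cell contact lists via a manifest
#'
#' The manifest is a two-column TSV (cell_id, path) pointing at per-cell
#' 4-column TSVs: chrom, bin_i, bin_j, count. With `positions = TRUE` the two
#' middle columns are bp positions, converted by `floor(pos/resolution)`.
#'
#' @param manifest path to the manifest TSV
#' @param resolution bin size in bp, used when `positions = TRUE`
#' @param positions are coordinates bp positions rather than bin indices?
#' @return named list of contact data.frames, ready for [vectorize_contacts()]
#' @export
read_contacts <- function(manifest, resolution = 1e6, positions = FALSE) {
  man <- utils::read.table(manifest, header = FALSE, sep = "\t",
                           colClasses = "character")
  base <- dirname(manifest)
  cells <- lapply(man[[2]], function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    df <- utils::read.table(p, header = FALSE, sep = "\t",
                            col.names = c("chrom", "bin_i", "bin_j", "count"))
    if (positions) {
      df$bin_i <- floor(df$bin_i / resolution)
      df$bin_j <- floor(df$bin_j / resolution)
    }
    df
  })
  stats::setNames(cells, man[[1]])
}

#' Library-size log-normalization
#'
#' `log(1 + scale * x_ij / t_j)` with `t_j` the column total; the standard
#' post-denoising normalization for expression and contact matrices alike.
#' Negative entries (possible in denoised output when clipping is off) must
#' be clipped before calling.
#'
#' @param x non-negative matrix or [count_matrix()]
#' @param scale multiplier before the log1p (default 1e4)
#' @return real matrix, same shape
#' @export
log_normalize <- function(x, scale = 1e4) {
  x <- as_dense(x)
  if (min(x) < 0)
    stop("negative entries: clip denoised output before log-normalizing")
  tj <- colSums(x)
  if (any(tj <= 0)) stop("column totals must be positive")
  log1p(sweep(x, 2L, tj / scale, "/"))
}
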