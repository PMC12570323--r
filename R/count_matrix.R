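#' Construct a count matrix container
#'
#' A `count_matrix` holds a features x cells matrix of non-negative counts
#' together with unique feature and cell identifiers. Cells whose total count
#' is zero carry no information under the sampling noise model and are removed
#' on construction (with a message); all downstream transforms require every
#' cell total \eqn{t_j > 0}.
#'
#' @param values numeric matrix (base or \pkg{Matrix} sparse), features in
#'   rows, cells in columns. A `count_matrix` is passed through unchanged.
#' @param feature_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)` or `g0001`-style minted ids.
#' @param cell_ids character vector of unique column identifiers; defaults to
#'   `colnames(values)` or `c0001`-style minted ids.
#' @param warn_nonint warn when entries are not integers (some platforms emit
#'   fractional "counts"; the noise model assumes true counts, see
#'   [classify_applicability()]).
#' @param allow_negative accept real-valued matrices with negative entries
#'   (e.g. re-reading denoised output written with clipping off); disables
#'   the non-negativity check and the zero-total cell filter.
#' @return An object of class `count_matrix` with elements `values`,
#'   `feature_ids`, `cell_ids`.
#' @examples
#' cm <- count_matrix(matrix(1, 3, 3))
#' dim(cm)
#' @export
count_matrix <- function(values, feature_ids = NULL, cell_ids = NULL,
                         warn_nonint = TRUE, allow_negative = FALSE) {
  if (inherits(values, "count_matrix")) return(values)
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop("'values' must be a matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("count matrix must have at least one feature and one cell")
  ent <- if (inherits(values, "Matrix")) values@x else values
  if (anyNA(ent) || any(!is.finite(ent)))
    stop("count matrix entries must be finite")
  if (!allow_negative && min(values) < 0)
    stop("count matrix entries must be non-negative")
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- mint_ids("g", nrow(values))
  if (is.null(cell_ids)) cell_ids <- mint_ids("c", ncol(values))
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length does not match row count")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length does not match column count")
  if (anyDuplicated(feature_ids)) stop("duplicate feature_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (warn_nonint) {
    x <- if (inherits(values, "Matrix")) values@x else values
    if (length(x) && max(abs(x - round(x))) > 1e-8)
      warning("non-integer entries: the sampling noise model assumes counts; ",
              "check classify_applicability() before denoising")
  }
  if (!allow_negative) {
    tj <- col_totals(values)
    keep <- tj > 0
    if (!any(keep)) stop("all cells have zero total count")
    if (!all(keep)) {
      message(sum(!keep), " cell(s) with zero total count removed")
      values <- values[, keep, drop = FALSE]
      cell_ids <- cell_ids[keep]
    }
  }
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 cell_ids = cell_ids),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mint_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

col_totals <- function(values) {
  if (inherits(values, "Matrix")) Matrix::colSums(values) else colSums(values)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d cells\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  total counts per cell: median %.0f [%.0f, %.0f]\n",
              stats::median(col_totals(x$values)),
              min(col_totals(x$values)), max(col_totals(x$values))))
  invisible(x)
}

#' Coerce a count_matrix to a dense base matrix
#' @param x a `count_matrix`
#' @return numeric matrix with feature/cell dimnames
#' @export
as_dense <- function(x) {
  v <- if (inherits(x, "count_matrix")) x$values else x
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  v
}

#' Read a count matrix from disk
#'
#' Supported layouts: MatrixMarket coordinate (`.mtx`) with sidecar
#' `features.tsv` and `cells.tsv` (one id per line, same directory, or supply
#' `features`/`cells` paths), and dense CSV/TSV with a header row of cell ids
#' and first column of feature ids. Orientation is features x cells; set
#' `transpose = TRUE` if the file stores cells x features. Zero-total cells
#' are removed on load.
#'
#' @param path path to the `.mtx` or dense table file
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`; `"auto"` keys on
#'   the file extension
#' @param transpose declare that the file is cells x features
#' @param features,cells optional explicit sidecar id files (mtx only)
#' @param allow_negative accept negative entries (denoised output re-read
#'   with clipping off); see [count_matrix()]
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                              transpose = FALSE,
                              features = NULL, cells = NULL,
                              allow_negative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    values <- tryCatch(Matrix::readMM(path),
                       error = function(e) stop("malformed MatrixMarket file: ",
                                                conditionMessage(e)))
    dir <- dirname(path)
    features <- features %||% file.path(dir, "features.tsv")
    cells <- cells %||% file.path(dir, "cells.tsv")
    fid <- if (file.exists(features)) readLines(features) else NULL
    cid <- if (file.exists(cells)) readLines(cells) else NULL
    if (transpose) {
      values <- Matrix::t(values)
      tmp <- fid; fid <- cid; cid <- tmp
    }
    count_matrix(values, feature_ids = fid, cell_ids = cid,
                 allow_negative = allow_negative)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                        check.names = FALSE, comment.char = ""),
      error = function(e) stop("malformed table header in ", path, ": ",
                               conditionMessage(e)))
    values <- as.matrix(df)
    if (!is.numeric(values)) stop("non-numeric entries in ", path)
    if (transpose) values <- t(values)
    count_matrix(values, allow_negative = allow_negative)
  }
}

#' Write a count matrix (or denoised real-valued matrix) to disk
#'
#' Dense CSV/TSV output carries full double precision (`%.10g`), so denoised
#' real-valued matrices survive a round trip to within 1e-6 relative error.
#'
#' @param x a [count_matrix()] or a numeric matrix with dimnames
#' @param path output path (`.mtx` output also writes `features.tsv` and
#'   `cells.tsv` beside it)
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(x, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (inherits(x, "count_matrix")) {
    values <- x$values; fid <- x$feature_ids; cid <- x$cell_ids
  } else {
    values <- x
    fid <- rownames(x) %||% mint_ids("g", nrow(x))
    cid <- colnames(x) %||% mint_ids("c", ncol(x))
  }
  if (length(fid) == 0L || nrow(values) == 0L) stop("empty feature list")
  if (anyNA(values) || any(!is.finite(as.numeric(values))))
    stop("matrix entries must be finite")
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    dir <- dirname(path)
    writeLines(fid, file.path(dir, "features.tsv"))
    writeLines(cid, file.path(dir, "cells.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("feature_id", cid), collapse = sep), con)
    body <- apply(as.matrix(values), 1L, function(r)
      paste(sprintf("%.10g", r), collapse = sep))
    writeLines(paste(fid, body, sep = sep), con)
  }
  invisible(path)
}

#' Read batch (or cell-type) labels and align them to a count matrix
#'
#' @param path two-column TSV: cell_id, label (no header, or header tolerated)
#' @param cm a [count_matrix()] whose cell order the labels are aligned to
#' @return character vector of labels in `cm`'s cell order
#' @export
read_labels <- function(path, cm) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L) stop("label file must have two columns (cell_id, label)")
  if (identical(tolower(df[1, 1]), "cell_id")) df <- df[-1, , drop = FALSE]
  idx <- match(cm$cell_ids, df[[1]])
  if (anyNA(idx)) {
    missing <- cm$cell_ids[is.na(idx)]
    stop("cells missing from label file: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  }
  labels <- df[[2]][idx]
  names(labels) <- cm$cell_ids
  labels
}

#' Align an in-memory label vector to a count matrix
#' @param labels named character vector or unnamed vector already in order
#' @param cm a [count_matrix()]
#' @return character vector in `cm`'s cell order
#' @export
align_labels <- function(labels, cm) {
  if (!is.null(names(labels))) {
    idx <- match(cm$cell_ids, names(labels))
    if (anyNA(idx)) stop("cells missing from labels: ",
                         paste(utils::head(cm$cell_ids[is.na(idx)], 5L),
                               collapse = ", "))
    labels <- labels[idx]
  } else if (length(labels) != length(cm$cell_ids)) {
    stop("label length does not match number of cells")
  }
  as.character(labels)
}
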