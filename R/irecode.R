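#' Denoise and batch-integrate in one pass
#'
#' Inserts a batch corrector `B` between projection and reconstruction:
#' `rc_inv(model, B(rc_ess(model, x), labels))`. Correction therefore acts on
#' the l* essential coordinates, never on the d-dimensional gene space, which
#' is what keeps its cost and accuracy independent of the feature dimension.
#' With the identity corrector (or a single batch under the reference
#' corrector) the result equals [rc_apply()] exactly.
#'
#' @param model a [recode_fit()] model
#' @param x a [count_matrix()] with matching features
#' @param labels batch labels, one per cell (named vectors are aligned by id)
#' @param corrector a batch corrector: `function(values, labels)` mapping an
#'   l* x n matrix to a matrix of identical shape. Defaults to
#'   [reference_corrector()].
#' @return d x n denoised, batch-integrated matrix
#' @examples
#' sim <- generate_celltype_batches(60, 120, seed = 1)
#' model <- recode_fit(sim$counts)
#' out <- irc_apply(model, sim$counts, sim$truth$batches)
#' @export
irc_apply <- function(model, x, labels, corrector = reference_corrector) {
  xm <- if (inherits(x, "count_matrix")) x else count_matrix(x, warn_nonint = FALSE)
  labels <- align_labels(labels, xm)
  e <- rc_ess(model, xm)
  corrected <- corrector(e$values, labels)
  if (!is.matrix(corrected) || !all(dim(corrected) == dim(e$values)))
    stop("batch corrector violated its contract: expected a ",
         nrow(e$values), " x ", ncol(e$values), " matrix")
  if (anyNA(corrected) || any(!is.finite(corrected)))
    stop("batch corrector returned non-finite values")
  e$values <- corrected
  rc_inv(model, e)
}

#' Centroid-matching reference batch corrector
#'
#' Per essential coordinate, subtracts each batch's centroid and adds back the
#' pooled (grand) centroid, so all batch centroids coincide while the grand
#' mean of the matrix is preserved exactly. A single batch is a no-op. This is
#' the built-in default; heavier correctors (Harmony-class methods) plug in
#' through [external_corrector_adapter()] or any conforming R function.
#'
#' @param values l* x n essential matrix
#' @param labels batch label per column
#' @return matrix of identical shape
#' @export
reference_corrector <- function(values, labels) {
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("label length does not match number of cells")
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) == 0L)) stop("empty batch group")
  if (length(groups) == 1L) return(values)
  grand <- rowMeans(values)
  out <- values
  for (idx in groups) {
    centroid <- rowMeans(values[, idx, drop = FALSE])
    out[, idx] <- values[, idx, drop = FALSE] - centroid + grand
  }
  out
}

#' Wrap an external command (or R function) as a batch corrector
#'
#' The file handshake: the essential matrix is written as a TSV whose rows are
#' essential coordinates and whose header holds cell ids, the labels as a
#' two-column TSV; the command is invoked as
#' `cmd <matrix.tsv> <labels.tsv> <out.tsv>` and must write a TSV of the same
#' shape. An R `function(values, labels)` is validated and passed through
#' under the same contract.
#'
#' @param cmd a command string, or an R function
#' @return a corrector function usable with [irc_apply()]
#' @export
external_corrector_adapter <- function(cmd) {
  if (is.function(cmd)) {
    force(cmd)
    return(function(values, labels) {
      out <- cmd(values, labels)
      if (!is.matrix(out) || !all(dim(out) == dim(values)))
        stop("external corrector returned a ",
             paste(dim(out), collapse = " x "), " matrix; expected ",
             paste(dim(values), collapse = " x "))
      out
    })
  }
  stopifnot(is.character(cmd), length(cmd) == 1L)
  function(values, labels) {
    dir <- tempfile("corrector_")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    f_in <- file.path(dir, "essential.tsv")
    f_lab <- file.path(dir, "labels.tsv")
    f_out <- file.path(dir, "corrected.tsv")
    cid <- colnames(values) %||% mint_ids("c", ncol(values))
    utils::write.table(
      stats::setNames(as.data.frame(values), cid), f_in,
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(cell_id = cid, label = labels), f_lab,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    status <- system(paste(cmd, shQuote(f_in), shQuote(f_lab), shQuote(f_out)))
    if (status != 0L) stop("external corrector exited with status ", status)
    if (!file.exists(f_out)) stop("external corrector produced no output file")
    out <- as.matrix(utils::read.table(f_out, header = TRUE, sep = "\t",
                                       check.names = FALSE))
    if (!all(dim(out) == dim(values)))
      stop("external corrector wrote a ", paste(dim(out), collapse = " x "),
           " matrix; expected ", paste(dim(values), collapse = " x "))
    unname(out)
  }
}
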