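#' Bundle spatial counts with coordinates
#'
#' @param counts a [count_matrix()] (genes x spots/cells)
#' @param coordinates data.frame with columns `x`, `y` and rownames (or a
#'   `cell_id` column) matching the count matrix cell ids
#' @return an object of class `spatial_table`
#' @export
spatial_table <- function(counts, coordinates) {
  counts <- count_matrix(counts, warn_nonint = FALSE)
  if (!is.null(coordinates$cell_id)) {
    rownames(coordinates) <- coordinates$cell_id
    coordinates$cell_id <- NULL
  }
  if (!all(c("x", "y") %in% colnames(coordinates)))
    stop("coordinates need columns 'x' and 'y'")
  idx <- match(counts$cell_ids, rownames(coordinates))
  if (anyNA(idx))
    stop("coordinates missing for cells: ",
         paste(utils::head(counts$cell_ids[is.na(idx)], 5L), collapse = ", "))
  structure(list(counts = counts,
                 coordinates = coordinates[idx, c("x", "y"), drop = FALSE]),
            class = "spatial_table")
}

#' Denoise a spatial transcriptomics table
#'
#' Runs the denoising transform on the gene expression counts only; spatial
#' coordinates are excluded from the model and pass through untouched.
#' Optionally attaches a log-normalized layer of the denoised counts
#' (negatives clipped for the log layer only).
#'
#' @param table a [spatial_table()]
#' @param config a [recode_config()]
#' @param log_layer also compute `log_normalized` from the denoised counts
#' @param scale log-normalization scale
#' @return the input `spatial_table` with added elements `denoised` (and
#'   `log_normalized` when requested) and `model`
#' @export
apply_spatial <- function(table, config = recode_config(), log_layer = TRUE,
                          scale = 1e4) {
  stopifnot(inherits(table, "spatial_table"))
  model <- recode_fit(table$counts, config)
  den <- rc_apply(model, table$counts)
  table$denoised <- den
  if (log_layer) table$log_normalized <- log_normalize(pmax(den, 0), scale)
  table$model <- model
  table
}

#' @export
print.spatial_table <- function(x, ...) {
  cat(sprintf("spatial_table: %d genes x %d spots%s\n",
              nrow(x$counts$values), ncol(x$counts$values),
              if (!is.null(x$denoised)) " (denoised)" else ""))
  invisible(x)
}
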