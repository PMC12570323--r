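#' Run configuration for the denoising transform
#'
#' Collects every tunable of the fitting pipeline in one validated object.
#'
#' @param variant `"original"` (eigenvalue modification only) or `"v2"`
#'   (additionally applies the sparse eigenvector modification).
#' @param fast use the truncated spectral path (leading eigenpairs plus the
#'   trace identity) instead of a full decomposition.
#' @param downsample_fraction fraction of cells used for learning when the
#'   dataset exceeds `downsample_threshold`; in (0, 1]. Default 0.2.
#' @param downsample_threshold cell count above which downsampling learning
#'   kicks in. Default 20000.
#' @param seed integer seed governing the learning-subset draw.
#' @param eq1_denominator `"as_printed"` divides the eigenvalue tail sum by
#'   `m - i + 1` (the printed estimator), `"tail_mean"` by the number of tail
#'   terms `m - i`.
#' @param clip_negative floor negative denoised entries at zero.
#' @return an object of class `recode_config`
#' @export
recode_config <- function(variant = c("original", "v2"),
                          fast = FALSE,
                          downsample_fraction = 0.2,
                          downsample_threshold = 20000L,
                          seed = 0L,
                          eq1_denominator = c("as_printed", "tail_mean"),
                          clip_negative = FALSE) {
  variant <- match.arg(variant)
  eq1_denominator <- match.arg(eq1_denominator)
  stopifnot(is.numeric(downsample_fraction), length(downsample_fraction) == 1L,
            downsample_fraction > 0, downsample_fraction <= 1,
            downsample_threshold >= 1)
  structure(list(variant = variant, fast = isTRUE(fast),
                 downsample_fraction = downsample_fraction,
                 downsample_threshold = as.integer(downsample_threshold),
                 seed = as.integer(seed),
                 eq1_denominator = eq1_denominator,
                 clip_negative = isTRUE(clip_negative)),
            class = "recode_config")
}

#' Read a key = value config file into a recode_config
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Unknown keys are an error. Values given in `overrides` win over the file.
#'
#' @param path path to the config file, or `NULL` for pure defaults
#' @param overrides named list of values overriding the file
#' @return a [recode_config()]
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    for (line in readLines(path)) {
      line <- sub("#.*$", "", line)
      if (!nzchar(trimws(line))) next
      kv <- strsplit(line, "[=:]", fixed = FALSE)[[1]]
      if (length(kv) != 2L) stop("cannot parse config line: ", line)
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(recode_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in c("downsample_fraction", "seed", "downsample_threshold"))
    if (!is.null(vals[[k]])) vals[[k]] <- as.numeric(vals[[k]])
  for (k in c("fast", "clip_negative"))
    if (!is.null(vals[[k]])) vals[[k]] <- as.logical(vals[[k]])
  do.call(recode_config, vals)
}
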