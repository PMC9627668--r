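#' Feature matrix container
#'
#' The central object of the pipeline: a numeric samples-by-features matrix of
#' metabolite ion intensities, tagged with a processing `stage`. Raw and
#' corrected stages hold strictly positive intensities; the `zscored` stage
#' holds reals with per-feature mean 0 and unit SD; `cellline_avg` holds one
#' row per cell line after replicate averaging.
#'
#' @param values numeric matrix with unique row names (sample or cell-line
#'   IDs) and unique column names (feature IDs).
#' @param stage processing stage, one of `"raw"`, `"drift_corrected"`,
#'   `"confluency_corrected"`, `"filtered"`, `"zscored"`, `"cellline_avg"`.
#' @return a `FeatureMatrix` (numeric matrix with a `stage` attribute).
#' @export
feature_matrix <- function(values, stage = "raw") {
  stages <- c("raw", "drift_corrected", "confluency_corrected",
              "filtered", "zscored", "cellline_avg")
  stage <- match.arg(stage, stages)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("sample and feature IDs must be unique")
  if (stage %in% c("raw", "drift_corrected", "confluency_corrected", "filtered")) {
    if (any(!is.finite(values)) || any(values < 0))
      stop("intensity-stage values must be finite and non-negative")
  }
  structure(values, stage = stage, class = c("FeatureMatrix", class(values)))
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d samples x %d features, stage '%s'\n",
              nrow(x), ncol(x), fm_stage(x)))
  invisible(x)
}

#' Processing stage of a FeatureMatrix
#' @param x a [feature_matrix()].
#' @return the stage string.
#' @export
fm_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) "raw" else s
}

#' Plain numeric values of a FeatureMatrix
#' @param x a [feature_matrix()].
#' @return the underlying numeric matrix without class or stage attributes.
#' @export
fm_values <- function(x) {
  y <- unclass(x)
  attr(y, "stage") <- NULL
  y
}

# internal: rebuild with new stage, preserving dimnames
fm_restage <- function(values, stage) feature_matrix(values, stage = stage)

# internal: check that meta covers the matrix rows, return meta aligned
# to the row order of `x`.
align_meta <- function(x, meta, cols = character()) {
  if (!is.data.frame(meta) || is.null(meta$sample_id))
    stop("`meta` must be a data.frame with a sample_id column")
  missing_cols <- setdiff(cols, names(meta))
  if (length(missing_cols))
    stop("`meta` is missing columns: ", paste(missing_cols, collapse = ", "))
  idx <- match(rownames(x), meta$sample_id)
  if (anyNA(idx))
    stop("metadata missing for samples: ",
         paste(utils::head(rownames(x)[is.na(idx)], 5), collapse = ", "))
  meta[idx, , drop = FALSE]
}

# internal: log10 view used for distances; z-scored matrices are used as-is
distance_values <- function(x) {
  v <- fm_values(x)
  if (fm_stage(x) %in% c("zscored", "cellline_avg")) return(v)
  if (any(v <= 0)) stop("intensities must be positive for log10 distances")
  log10(v)
}
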