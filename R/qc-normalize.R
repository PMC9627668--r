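#' Replicate ROC AUC
#'
#' Reproducibility metric: all pairwise Euclidean distances between samples
#' (on log10 intensities; z-scored stages are used as-is) are scored by the
#' classifier "smaller distance implies replicate pair". A pair is positive at
#' the technical level when the two samples share cell line and biological
#' replicate, and at the biological level when they share the cell line but
#' not the biological replicate; all other pairs are negative. Ties contribute
#' 0.5 via midranks (Wilcoxon formulation).
#'
#' @param matrix a [feature_matrix()].
#' @param meta sample metadata with `cell_line` and `bio_rep`.
#' @param level `"technical"` or `"biological"`.
#' @return AUC in `[0, 1]`.
#' @export
replicate_roc_auc <- function(matrix, meta, level = c("technical", "biological")) {
  level <- match.arg(level)
  if (nrow(matrix) < 2) stop("need at least 2 samples")
  meta <- align_meta(matrix, meta, c("cell_line", "bio_rep"))
  d <- as.vector(stats::dist(distance_values(matrix)))
  n <- nrow(matrix)
  ij <- utils::combn(n, 2)
  same_line <- meta$cell_line[ij[1, ]] == meta$cell_line[ij[2, ]]
  same_bio <- same_line & meta$bio_rep[ij[1, ]] == meta$bio_rep[ij[2, ]]
  pos <- if (level == "technical") same_bio else same_line & !same_bio
  if (!any(pos) || all(pos))
    stop("AUC undefined: need both replicate and non-replicate pairs")
  r <- rank(d)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[!pos]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

# lowess fit evaluated back at the original x positions
lowess_fit <- function(x, y, span, iter = 2L) {
  l <- stats::lowess(x, y, f = span, iter = iter)
  stats::approx(l$x, l$y, xout = x, rule = 2, ties = mean)$y
}

#' Correct injection-order drift
#'
#' Fits a Lowess curve of natural-log intensity versus injection index for
#' each feature independently, subtracts it, and re-centres each feature at
#' its pre-correction log mean, so the smoothed trend of the corrected
#' feature over injection order is flat.
#'
#' @param matrix a raw-stage [feature_matrix()].
#' @param meta sample metadata with `injection_index`.
#' @param span Lowess span (fraction of points in the local window).
#' @param iter robustness iterations.
#' @return a drift-corrected [feature_matrix()].
#' @export
correct_injection_drift <- function(matrix, meta, span = 0.3, iter = 2L) {
  meta <- align_meta(matrix, meta, "injection_index")
  if (nrow(matrix) < 10) stop("fewer than 10 injections: trend not estimable")
  lv <- log(fm_values(matrix))
  x <- meta$injection_index
  for (j in seq_len(ncol(lv))) {
    fit <- lowess_fit(x, lv[, j], span, iter)
    lv[, j] <- lv[, j] - fit + mean(lv[, j])
  }
  fm_restage(exp(lv), "drift_corrected")
}

#' Drop low-intensity injections
#'
#' Removes every sample whose log2 total ion intensity falls below the
#' threshold.
#'
#' @param matrix an intensity-stage [feature_matrix()].
#' @param threshold_log2_sum cutoff on `log2(sum of intensities)`.
#' @return list with the reduced `matrix` and the `removed` sample IDs.
#' @export
drop_low_intensity_injections <- function(matrix, threshold_log2_sum = 25) {
  s <- log2(rowSums(fm_values(matrix)))
  drop <- s < threshold_log2_sum
  if (all(drop)) stop("all samples fall below the intensity threshold")
  list(matrix = fm_restage(fm_values(matrix)[!drop, , drop = FALSE],
                           fm_stage(matrix)),
       removed = rownames(matrix)[drop])
}

#' Correct confluency dependence of total intensity
#'
#' Fits a Lowess curve of per-sample log total intensity versus confluency
#' and rescales each sample's intensities by the fitted multiplicative
#' factor, removing the dependence of total intensity on confluency.
#'
#' @param matrix an intensity-stage [feature_matrix()].
#' @param meta sample metadata with `confluency`.
#' @param span Lowess span.
#' @param iter robustness iterations.
#' @return a confluency-corrected [feature_matrix()].
#' @export
correct_confluency <- function(matrix, meta, span = 0.5, iter = 2L) {
  meta <- align_meta(matrix, meta, "confluency")
  if (nrow(matrix) < 10) stop("fewer than 10 samples: trend not estimable")
  conf <- meta$confluency
  if (stats::sd(conf) == 0) {
    warning("constant confluency: returning input unchanged")
    return(fm_restage(fm_values(matrix), "confluency_corrected"))
  }
  tot <- log(rowSums(fm_values(matrix)))
  fit <- lowess_fit(conf, tot, span, iter)
  factor <- fit - mean(fit)
  fm_restage(fm_values(matrix) * exp(-factor), "confluency_corrected")
}

# one-way ANOVA p-value, vectorised over the columns of Y
anova_pvalues <- function(Y, g) {
  g <- factor(g)
  if (nlevels(g) < 2) return(rep(NA_real_, ncol(Y)))
  n <- nrow(Y); k <- nlevels(g)
  gm <- rowsum(Y, g) / as.vector(table(g))
  fitted <- gm[as.integer(g), , drop = FALSE]
  ssb <- colSums((fitted - matrix(colMeans(Y), n, ncol(Y), byrow = TRUE))^2)
  ssw <- colSums((Y - fitted)^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p
}

#' Batch/plate feature filter tuned by replicate AUC
#'
#' Computes one-way ANOVA p-values for batch and for plate on each feature's
#' log intensities, ranks features by `min(p_batch, p_plate)`, and sweeps
#' candidate removal counts (every count up to 50, then steps of 5),
#' recomputing the biological replicate ROC AUC after each removal. The count
#' with the best AUC wins (ties go to the smallest count).
#'
#' @param matrix an intensity-stage [feature_matrix()].
#' @param meta sample metadata with `batch`, `plate`, `cell_line`, `bio_rep`.
#' @param max_remove largest removal count considered.
#' @return list with the filtered `matrix` and a `report` containing
#'   `auc_biological` (after filtering), `auc_technical`, `removed_features`,
#'   `anova_pvalues` and the `sweep_curve` of (n_removed, auc_biological).
#' @export
batch_plate_filter <- function(matrix, meta, max_remove = 50) {
  meta <- align_meta(matrix, meta, c("batch", "plate", "cell_line", "bio_rep"))
  nf <- ncol(matrix)
  if (max_remove >= nf) stop("`max_remove` must be smaller than the feature count")
  n_batch <- length(unique(meta$batch))
  n_plate <- length(unique(meta$plate))
  if (n_batch < 2 && n_plate < 2)
    stop("need at least 2 batches or 2 plates")
  lv <- log(fm_values(matrix))
  p_batch <- anova_pvalues(lv, meta$batch)
  p_plate <- anova_pvalues(lv, meta$plate)
  score <- pmin(p_batch, p_plate, na.rm = TRUE)
  ord <- order(score)
  grid <- if (max_remove <= 50) 0:max_remove else
    unique(c(0:50, seq.int(55, max_remove, by = 5), max_remove))
  aucs <- vapply(grid, function(m) {
    keep <- if (m == 0) seq_len(nf) else setdiff(seq_len(nf), ord[seq_len(m)])
    sub <- fm_restage(fm_values(matrix)[, keep, drop = FALSE], fm_stage(matrix))
    replicate_roc_auc(sub, meta, "biological")
  }, 0)
  best <- grid[which.max(aucs)]  # which.max returns the first (smallest) tie
  removed <- if (best == 0) character(0) else colnames(matrix)[ord[seq_len(best)]]
  keep <- setdiff(colnames(matrix), removed)
  out <- fm_restage(fm_values(matrix)[, keep, drop = FALSE], "filtered")
  report <- list(
    auc_biological = max(aucs),
    auc_technical = replicate_roc_auc(out, meta, "technical"),
    removed_injections = character(0),
    removed_features = removed,
    anova_pvalues = data.frame(feature = colnames(matrix),
                               p_batch = p_batch, p_plate = p_plate,
                               stringsAsFactors = FALSE),
    sweep_curve = data.frame(n_removed = grid, auc_biological = aucs)
  )
  list(matrix = out, report = report)
}

#' Z-score features
#'
#' Standardises each feature across samples to mean 0 and sample SD 1.
#' Intensity stages are log10-transformed first; already z-scored input is
#' (numerically) a fixed point. Zero-variance features are dropped with a
#' warning.
#'
#' @param matrix a [feature_matrix()] with at least 2 rows.
#' @return a zscored-stage [feature_matrix()].
#' @export
zscore_features <- function(matrix) {
  if (nrow(matrix) < 2) stop("z-scoring needs at least 2 samples")
  v <- fm_values(matrix)
  if (!fm_stage(matrix) %in% c("zscored", "cellline_avg")) v <- log10(v)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance features: ",
            paste(utils::head(colnames(v)[sds == 0], 5), collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
  }
  fm_restage(scale(v)[, , drop = FALSE], "zscored")
}

#' Average replicates to the cell-line level
#'
#' Technical replicates are first averaged within each biological replicate;
#' biological replicates are then averaged with equal weight, regardless of
#' how many technical replicates each one retained.
#'
#' @param matrix a [feature_matrix()]. Z-scored input feeds the association
#'   analyses; intensity input with `log10 = TRUE` feeds the rank-based
#'   pathway activity, which needs the bulk abundance ordering that
#'   z-scoring would erase.
#' @param meta sample metadata with `cell_line` and `bio_rep`.
#' @param log10 average log10 intensities (geometric means) instead of the
#'   values themselves; only meaningful for intensity stages.
#' @return a cellline_avg-stage [feature_matrix()] with one row per cell line.
#' @export
average_biological_replicates <- function(matrix, meta, log10 = FALSE) {
  meta <- align_meta(matrix, meta, c("cell_line", "bio_rep"))
  v <- fm_values(matrix)
  if (log10) {
    if (any(v <= 0)) stop("log10 averaging needs positive intensities")
    v <- log10(v)
  }
  bio_key <- paste(meta$cell_line, meta$bio_rep, sep = "\r")
  bio_means <- rowsum(v, bio_key) / as.vector(table(bio_key)[sort(unique(bio_key))])
  bio_line <- sub("\r.*$", "", rownames(bio_means))
  line_means <- rowsum(bio_means, bio_line) /
    as.vector(table(bio_line)[sort(unique(bio_line))])
  fm_restage(line_means, "cellline_avg")
}
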