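#' Per-cell-line rank profile against the bulk
#'
#' Features are ranked by mean value across cell lines (rank 1 = largest,
#' average ranks on ties) and again within each cell line; the profile records
#' `delta = bulk_rank - cell_line_rank`, so positive delta means the feature
#' sits higher (more abundant) in that line than in the bulk.
#'
#' @param matrix a cellline_avg-stage [feature_matrix()].
#' @return a `RankProfile` list with `bulk_rank`, `sample_rank` (lines x
#'   features) and `delta`.
#' @export
compute_rank_profile <- function(matrix) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  v <- fm_values(matrix)
  if (ncol(v) < 2) stop("need at least 2 features")
  bulk_rank <- rank(-colMeans(v), ties.method = "average")
  sample_rank <- t(apply(v, 1, function(row) {
    if (stats::sd(row) == 0)
      warning("all-tied feature values in a cell line: average ranks used")
    rank(-row, ties.method = "average")
  }))
  dimnames(sample_rank) <- dimnames(v)
  delta <- sweep(-sample_rank, 2, bulk_rank, FUN = "+")  # bulk - sample
  structure(list(bulk_rank = bulk_rank, sample_rank = sample_rank,
                 delta = delta), class = "RankProfile")
}

# minimum hypergeometric tail over prefixes; `pos` are the (sorted) ranks of
# the K members among N. The minimum over all prefix lengths is attained at a
# member position, since the upper tail only grows between members.
mhg_statistic <- function(pos, N, K) {
  tails <- stats::phyper(seq_len(K) - 1, K, N - K, pos, lower.tail = FALSE)
  i <- which.min(tails)
  list(s = tails[i], k_at_min = i, n_at_min = pos[i])
}

#' Minimum-hypergeometric (mHG) rank enrichment test
#'
#' For a ranked boolean membership list, computes for every prefix length the
#' hypergeometric upper-tail probability of the observed member count, and
#' takes the minimum `s` over prefixes. Because `s` is a minimum over many
#' dependent tails it is not a p-value; it is calibrated either by
#' permutation (exact enumeration of all `choose(N, K)` member placements
#' when that count is at most `exhaustive_limit`, otherwise Monte-Carlo with
#' +1 smoothing) or by a Bonferroni bound `min(1, s * K)` over the K
#' informative prefixes.
#'
#' @param ranked_flags logical vector: membership down the ranked list.
#' @param calibration `"permutation"` or `"bonferroni"`.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param exhaustive_limit enumerate all placements when
#'   `choose(N, K) <= exhaustive_limit`.
#' @return list with `s` (the mHG statistic), `p` (calibrated p-value),
#'   `k_at_min`, `n_at_min`, and `exhaustive` flag.
#' @export
min_hypergeometric <- function(ranked_flags,
                               calibration = c("permutation", "bonferroni"),
                               n_perm = 2000, seed = 1,
                               exhaustive_limit = 5000) {
  calibration <- match.arg(calibration)
  if (!length(ranked_flags)) stop("empty ranked list")
  flags <- as.logical(ranked_flags)
  N <- length(flags); K <- sum(flags)
  if (K == 0) stop("no members in the ranked list")
  if (K == N)
    return(list(s = 1, p = 1, k_at_min = K, n_at_min = N, exhaustive = TRUE))
  obs <- mhg_statistic(which(flags), N, K)
  tol <- 1 + 1e-9
  if (calibration == "bonferroni")
    return(c(obs, list(p = min(1, obs$s * K), exhaustive = FALSE)))
  if (choose(N, K) <= exhaustive_limit) {
    all_s <- utils::combn(N, K, function(pos) mhg_statistic(pos, N, K)$s)
    p <- mean(all_s <= obs$s * tol)
    return(c(obs, list(p = p, exhaustive = TRUE)))
  }
  null_s <- withr::with_seed(seed, {
    pos <- vapply(seq_len(n_perm),
                  function(i) sort.int(sample.int(N, K)), integer(K))
    tails <- matrix(stats::phyper(rep(seq_len(K) - 1, n_perm), K, N - K,
                                  as.vector(pos), lower.tail = FALSE), K)
    do.call(pmin, lapply(seq_len(K), function(k) tails[k, ]))
  })
  p <- (sum(null_s <= obs$s * tol) + 1) / (n_perm + 1)
  c(obs, list(p = p, exhaustive = FALSE))
}

#' Rank-based pathway activity per cell line
#'
#' For each (cell line, pathway): the rank-sum change is the sum of the rank
#' profile's delta over the pathway members; significance comes from the mHG
#' test applied to the features ordered by delta descending (increase) and
#' ascending (decrease), reporting the smaller p with its direction. A
#' direction label is assigned when p < alpha and |rank-sum change| exceeds
#' `rank_sum_threshold * n_features / 1099` (the threshold is calibrated for
#' a 1,099-feature panel and scales linearly with panel size). A pathway is
#' flagged for reporting when at least `min_frac_significant` of cell lines
#' reach p < alpha.
#'
#' @param matrix a cellline_avg-stage [feature_matrix()].
#' @param db a [pathway_db()]; members absent from the matrix are dropped,
#'   pathways left with fewer than 3 members are excluded.
#' @param alpha per-cell-line significance level.
#' @param min_frac_significant reporting threshold on the fraction of lines.
#' @param rank_sum_threshold direction-labelling cutoff at 1,099 features.
#' @param calibration,n_perm,seed passed to [min_hypergeometric()];
#'   Bonferroni is the speed-friendly default for the per-line scan.
#' @return an `ActivityMatrix` list with matrices `rank_sum_change`,
#'   `pvalue`, `direction`, the `flagged` pathway names, and `params`.
#' @export
pathway_activity <- function(matrix, db, alpha = 0.05,
                             min_frac_significant = 0.40,
                             rank_sum_threshold = 350,
                             calibration = "bonferroni",
                             n_perm = 2000, seed = 1) {
  stopifnot(inherits(db, "PathwayDB"))
  rp <- compute_rank_profile(matrix)
  feats <- colnames(matrix)
  members <- lapply(db$pathways, intersect, feats)
  dropped <- names(members)[lengths(members) < 3]
  if (length(dropped))
    message("excluding pathways with < 3 measured members: ",
            paste(dropped, collapse = ", "))
  members <- members[lengths(members) >= 3]
  if (!length(members)) stop("no pathway retains 3 or more measured members")
  lines <- rownames(matrix)
  nf <- length(feats)
  thr <- rank_sum_threshold * nf / 1099
  rsc <- pv <- matrix(NA_real_, length(lines), length(members),
                      dimnames = list(lines, names(members)))
  dir <- matrix("none", length(lines), length(members),
                dimnames = list(lines, names(members)))
  member_idx <- lapply(members, match, feats)
  for (l in seq_along(lines)) {
    d <- rp$delta[l, ]
    ord_up <- order(d, decreasing = TRUE)
    ord_dn <- rev(ord_up)
    for (pwi in seq_along(members)) {
      idx <- member_idx[[pwi]]
      rsc[l, pwi] <- sum(d[idx])
      flag <- logical(nf); flag[idx] <- TRUE
      up <- min_hypergeometric(flag[ord_up], calibration, n_perm, seed)
      dn <- min_hypergeometric(flag[ord_dn], calibration, n_perm, seed)
      if (up$p <= dn$p) {
        pv[l, pwi] <- up$p
        if (up$p < alpha && rsc[l, pwi] > thr) dir[l, pwi] <- "increased"
      } else {
        pv[l, pwi] <- dn$p
        if (dn$p < alpha && rsc[l, pwi] < -thr) dir[l, pwi] <- "decreased"
      }
    }
  }
  frac_sig <- colMeans(pv < alpha)
  structure(list(rank_sum_change = rsc, pvalue = pv, direction = dir,
                 flagged = names(members)[frac_sig >= min_frac_significant],
                 params = list(alpha = alpha,
                               min_frac_significant = min_frac_significant,
                               rank_sum_threshold = rank_sum_threshold,
                               threshold_scaled = thr, n_features = nf)),
            class = "ActivityMatrix")
}

#' Doubling-time regression per pathway
#'
#' Ordinary least squares of reported doubling time on each pathway's
#' rank-sum change across cell lines, with Pearson r, two-sided p and BH
#' adjustment across pathways.
#'
#' @param activity an `ActivityMatrix` from [pathway_activity()].
#' @param meta sample metadata with `cell_line` and `doubling_time`.
#' @return data.frame with pathway, slope, r, p_raw, p_adjusted, n.
#' @export
doubling_time_regression <- function(activity, meta) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  lines <- rownames(activity$rank_sum_change)
  dt <- meta$doubling_time[match(lines, meta$cell_line)]
  ok <- !is.na(dt)
  if (sum(ok) < 5) stop("need at least 5 cell lines with doubling times")
  res <- lapply(colnames(activity$rank_sum_change), function(pw) {
    x <- activity$rank_sum_change[ok, pw]
    y <- dt[ok]
    if (stats::sd(x) == 0) {
      message("skipping constant pathway: ", pw)
      return(NULL)
    }
    fit <- stats::lm(y ~ x)
    # a perfect fit triggers an "essentially perfect fit" warning; the p
    # floor below already handles that case
    sm <- suppressWarnings(summary(fit))$coefficients
    p <- sm["x", "Pr(>|t|)"]
    data.frame(pathway = pw, slope = sm["x", "Estimate"],
               r = stats::cor(x, y),
               p_raw = max(p, .Machine$double.xmin),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no pathway with variable rank-sum change")
  out$p_adjusted <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Over-representation analysis (hypergeometric ORA)
#'
#' Upper-tail hypergeometric probability of the overlap between a selected ID
#' set and each pathway within a universe, BH-adjusted across pathways.
#'
#' @param selection character vector, subset of `universe`.
#' @param db a [pathway_db()].
#' @param universe universe IDs; defaults to the database universe.
#' @return data.frame with pathway, n_members, overlap, p_raw, p_adjusted,
#'   ordered by p_raw.
#' @export
ora <- function(selection, db, universe = db$universe) {
  stopifnot(inherits(db, "PathwayDB"))
  if (!length(selection)) stop("empty selection")
  selection <- unique(as.character(selection))
  if (!all(selection %in% universe))
    stop("selection contains IDs outside the universe")
  N <- length(universe); n <- length(selection)
  rows <- lapply(names(db$pathways), function(pw) {
    memb <- intersect(db$pathways[[pw]], universe)
    K <- length(memb)
    if (K == 0) return(NULL)
    k <- length(intersect(selection, memb))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, n_members = K, overlap = k, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway overlaps the universe")
  out$p_adjusted <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, capped at 1, in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}
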