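#' Tissue adjacency clustering score
#'
#' Counts adjacent positions with equal labels in a given ordering (e.g. a
#' dendrogram leaf order); the statistic behind the permutation test of
#' whether same-tissue samples cluster together.
#'
#' @param ordered_labels character/factor vector in display order.
#' @return integer count of equal adjacent pairs.
#' @export
tissue_adjacency_score <- function(ordered_labels) {
  x <- as.character(ordered_labels)
  if (!length(x)) stop("empty label list")
  if (length(x) < 2) stop("need at least 2 labels")
  sum(x[-1] == x[-length(x)])
}

# all distinct orderings of a label multiset (lexicographic recursion)
multiset_permutations <- function(counts) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  labels <- names(counts)
  out <- vector("list", 0)
  rec <- function(prefix, counts) {
    if (sum(counts) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (l in labels) {
      if (counts[[l]] > 0L) {
        counts[[l]] <- counts[[l]] - 1L
        rec(c(prefix, l), counts)
        counts[[l]] <- counts[[l]] + 1L
      }
    }
  }
  rec(character(0), counts)
  out
}

#' Permutation p-value for label clustering
#'
#' Upper-tail p-value for the observed [tissue_adjacency_score()] against
#' label shuffles. When the number of distinct multiset orderings is at most
#' `factorial(exhaustive_limit)`, all orderings are enumerated and the exact
#' null fraction is returned; otherwise `n_perm` seeded Monte-Carlo shuffles
#' are drawn and the +1-smoothed estimate
#' `(#{null >= observed} + 1) / (n_perm + 1)` is reported, which can never
#' reach zero.
#'
#' @param observed_order label vector in observed order.
#' @param n_perm Monte-Carlo permutations.
#' @param seed integer seed.
#' @param exhaustive_limit enumerate exhaustively below
#'   `factorial(exhaustive_limit)` distinct orderings.
#' @return a `PermutationResult` list: `observed`, `null_samples`, `p`,
#'   `n_perm`, `exhaustive`, `seed`.
#' @export
permutation_pvalue <- function(observed_order, n_perm = 10000, seed = 1,
                               exhaustive_limit = 8) {
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  x <- as.character(observed_order)
  obs <- tissue_adjacency_score(x)
  counts <- table(x)
  if (length(counts) == 1)
    return(structure(list(observed = obs, null_samples = obs, p = 1,
                          n_perm = 0L, exhaustive = TRUE, seed = seed),
                     class = "PermutationResult"))
  n_distinct <- exp(lgamma(length(x) + 1) - sum(lgamma(counts + 1)))
  if (n_distinct <= factorial(exhaustive_limit) + 0.5) {
    perms <- multiset_permutations(counts)
    null <- vapply(perms, tissue_adjacency_score, 0L)
    p <- mean(null >= obs)
    return(structure(list(observed = obs, null_samples = null, p = p,
                          n_perm = length(null), exhaustive = TRUE,
                          seed = seed),
                     class = "PermutationResult"))
  }
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    tissue_adjacency_score(sample(x))
  }, 0L))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(list(observed = obs, null_samples = null, p = p,
                 n_perm = n_perm, exhaustive = FALSE, seed = seed),
            class = "PermutationResult")
}

#' Cross-dataset per-metabolite concordance
#'
#' For every feature shared by two cell-line-level matrices, the Pearson
#' correlation across shared cell lines is compared against a null built by
#' permuting the cell-line assignment of the second matrix; upper-tail
#' +1-smoothed p-values are BH-adjusted across features.
#'
#' @param matrix_a,matrix_b cell-line-level [feature_matrix()] objects.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return data.frame with feature, r, p_raw, p_adjusted.
#' @export
dataset_concordance <- function(matrix_a, matrix_b, n_perm = 1000, seed = 1) {
  A <- fm_values(matrix_a); B <- fm_values(matrix_b)
  lines <- intersect(rownames(A), rownames(B))
  feats <- intersect(colnames(A), colnames(B))
  if (length(lines) < 5) stop("need at least 5 shared cell lines")
  if (!length(feats)) stop("no shared features")
  A <- A[lines, feats, drop = FALSE]
  B <- B[lines, feats, drop = FALSE]
  n <- length(lines)
  Az <- scale(A); Bz <- scale(B)
  ok <- !(apply(A, 2, stats::sd) == 0 | apply(B, 2, stats::sd) == 0)
  Az <- Az[, ok, drop = FALSE]; Bz <- Bz[, ok, drop = FALSE]
  r_obs <- colSums(Az * Bz) / (n - 1)
  exceed <- withr::with_seed(seed, {
    cnt <- numeric(ncol(Az))
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      r_null <- colSums(Az[perm, , drop = FALSE] * Bz) / (n - 1)
      cnt <- cnt + (r_null >= r_obs)
    }
    cnt
  })
  p <- (exceed + 1) / (n_perm + 1)
  data.frame(feature = colnames(Az), r = unname(r_obs), p_raw = unname(p),
             p_adjusted = bh_adjust(p), stringsAsFactors = FALSE)
}
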