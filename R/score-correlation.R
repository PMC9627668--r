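#' Correlate a per-cell-line score with every metabolite
#'
#' Pearson correlation between one score column (transcriptional-program
#' activity, TF activity, ln IC50, doubling time, ...) and each feature over
#' the cell lines shared by the score table and the matrix. Zero-variance
#' features are skipped.
#'
#' @param matrix a cell-line-level [feature_matrix()].
#' @param scores numeric matrix or data.frame (cell lines x scores) with row
#'   names, or a named numeric vector.
#' @param score_name column to use (ignored for a vector).
#' @return named numeric vector of Pearson r per feature.
#' @export
metabolite_score_correlation <- function(matrix, scores, score_name = NULL) {
  v <- fm_values(matrix)
  if (is.vector(scores) && !is.null(names(scores))) {
    s <- scores
  } else {
    scores <- as.matrix(scores)
    if (is.null(score_name) || !score_name %in% colnames(scores))
      stop("`score_name` must name a column of `scores`")
    s <- scores[, score_name]
    names(s) <- rownames(scores)
  }
  shared <- intersect(rownames(v), names(s)[!is.na(s)])
  if (length(shared) < 5) stop("need at least 5 overlapping cell lines")
  s <- s[shared]
  if (stats::sd(s) == 0) stop("score is constant over the shared cell lines")
  sub <- v[shared, , drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  r <- suppressWarnings(as.vector(stats::cor(s, sub[, sds > 0, drop = FALSE])))
  stats::setNames(r, colnames(sub)[sds > 0])
}

#' mHG pathway enrichment of a correlation profile
#'
#' Features are ranked by |r| descending; each pathway with at least 3
#' measured members gets a minimum-hypergeometric p for the concentration of
#' its members near the top, a direction equal to the sign of the mean r of
#' its members, BH adjustment across pathways, and the signed statistic
#' `-log10(p_adjusted) * direction`.
#'
#' @param correlations named numeric vector from
#'   [metabolite_score_correlation()].
#' @param db a [pathway_db()].
#' @param calibration,n_perm,seed passed to [min_hypergeometric()].
#' @return data.frame with pathway, n_members, s, p_raw, p_adjusted,
#'   direction, signed_stat, k_at_min.
#' @export
pathway_score_enrichment <- function(correlations, db,
                                     calibration = "bonferroni",
                                     n_perm = 2000, seed = 1) {
  stopifnot(inherits(db, "PathwayDB"))
  r <- correlations[!is.na(correlations)]
  feats <- names(r)
  members <- lapply(db$pathways, intersect, feats)
  members <- members[lengths(members) >= 3]
  if (!length(members)) stop("no pathway with 3 or more measured members")
  ord <- order(-abs(r), feats)
  ranked <- feats[ord]
  degenerate <- all(r == 0)
  rows <- lapply(names(members), function(pw) {
    memb <- members[[pw]]
    if (degenerate) {
      mh <- list(s = 1, p = 1, k_at_min = NA_integer_)
    } else {
      mh <- min_hypergeometric(ranked %in% memb, calibration, n_perm, seed)
    }
    data.frame(pathway = pw, n_members = length(memb), s = mh$s,
               p_raw = mh$p, direction = sign(mean(r[memb])),
               k_at_min = mh$k_at_min, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$signed_stat <- -log10(out$p_adjusted) * out$direction
  out <- out[, c("pathway", "n_members", "s", "p_raw", "p_adjusted",
                 "direction", "signed_stat", "k_at_min")]
  rownames(out) <- NULL
  out
}

#' Drug-by-pathway signed sensitivity profiles
#'
#' For each drug's ln IC50 vector, runs [metabolite_score_correlation()] and
#' [pathway_score_enrichment()]. Sign convention: positive means higher
#' pathway activity associates with higher IC50 (insensitivity), negative
#' with sensitivity. Drugs with constant IC50 over the shared lines are
#' skipped with a message.
#'
#' @param matrix a cell-line-level [feature_matrix()].
#' @param drugs numeric matrix (cell lines x drugs) of ln IC50.
#' @param db a [pathway_db()].
#' @param calibration,n_perm,seed passed to [min_hypergeometric()].
#' @return a `DrugPathwayProfile` list with matrices `signed_stat` and
#'   `p_adjusted` (drug x pathway).
#' @export
drug_pathway_profiles <- function(matrix, drugs, db,
                                  calibration = "bonferroni",
                                  n_perm = 2000, seed = 1) {
  drugs <- as.matrix(drugs)
  profs <- list()
  for (d in colnames(drugs)) {
    res <- tryCatch({
      r <- metabolite_score_correlation(matrix, drugs, d)
      pathway_score_enrichment(r, db, calibration, n_perm, seed)
    }, error = function(e) {
      message("skipping drug ", d, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) profs[[d]] <- res
  }
  if (!length(profs)) stop("no drug could be profiled")
  pws <- profs[[1]]$pathway
  signed <- t(vapply(profs, function(p) p$signed_stat[match(pws, p$pathway)],
                     numeric(length(pws))))
  padj <- t(vapply(profs, function(p) p$p_adjusted[match(pws, p$pathway)],
                   numeric(length(pws))))
  colnames(signed) <- colnames(padj) <- pws
  structure(list(signed_stat = signed, p_adjusted = padj),
            class = "DrugPathwayProfile")
}

#' Drug-pair anticorrelation of pathway profiles
#'
#' Pearson correlation between every two drugs' signed pathway vectors;
#' strongly negative pairs have opposite metabolic sensitivity profiles and
#' are candidate synergies. Drugs with constant profiles are excluded.
#'
#' @param profiles a `DrugPathwayProfile`.
#' @return list with the symmetric correlation `matrix` and a `pairs`
#'   data.frame (drug_a, drug_b, profile_r) sorted ascending (most
#'   anticorrelated first).
#' @export
drug_pair_anticorrelation <- function(profiles) {
  stopifnot(inherits(profiles, "DrugPathwayProfile"))
  S <- profiles$signed_stat
  keep <- apply(S, 1, stats::sd) > 0
  if (any(!keep))
    message("excluding drugs with constant profiles: ",
            paste(rownames(S)[!keep], collapse = ", "))
  S <- S[keep, , drop = FALSE]
  if (nrow(S) < 2) stop("need at least 2 drugs with variable profiles")
  if (ncol(S) < 3) stop("need at least 3 shared pathways")
  R <- stats::cor(t(S))
  ij <- utils::combn(nrow(S), 2)
  pairs <- data.frame(drug_a = rownames(S)[ij[1, ]],
                      drug_b = rownames(S)[ij[2, ]],
                      profile_r = R[t(ij)], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$profile_r), ]
  rownames(pairs) <- NULL
  list(matrix = R, pairs = pairs)
}

# canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Overlay known synergies on the anticorrelation ranking
#'
#' Joins a known-synergy table (unordered drug pairs with ZIP scores;
#' synergy means ZIP > 0) onto the profiled pairs and tests, via the mHG
#' statistic down the ascending-r ranking, whether synergistic pairs
#' concentrate among the most anticorrelated ones.
#'
#' @param anticorrelations result of [drug_pair_anticorrelation()].
#' @param synergies data.frame with `drug_a`, `drug_b`, `zip_score`.
#' @param calibration,n_perm,seed passed to [min_hypergeometric()].
#' @return list with `table` (pair, profile_r, known_synergy) and
#'   `enrichment` (the mHG result).
#' @export
synergy_overlay <- function(anticorrelations, synergies,
                            calibration = "permutation", n_perm = 2000,
                            seed = 1) {
  pairs <- anticorrelations$pairs
  if (!nrow(synergies)) stop("empty synergy table")
  syn_key <- pair_key(synergies$drug_a, synergies$drug_b)
  syn_flag <- stats::setNames(synergies$zip_score > 0, syn_key)
  key <- pair_key(pairs$drug_a, pairs$drug_b)
  known <- key %in% syn_key
  if (!any(known)) stop("no overlap between synergy table and profiled drugs")
  pairs$known_synergy <- known & unname(syn_flag[key])
  pairs$known_synergy[is.na(pairs$known_synergy)] <- FALSE
  enr <- if (any(pairs$known_synergy)) {
    min_hypergeometric(pairs$known_synergy, calibration, n_perm, seed)
  } else {
    list(s = 1, p = 1, k_at_min = NA_integer_, n_at_min = NA_integer_,
         exhaustive = TRUE)
  }
  list(table = pairs, enrichment = enr)
}
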