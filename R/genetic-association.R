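#' Wide mutation-status matrix
#'
#' Converts a long (cell_line, gene, status) table into a cell-line x gene
#' character matrix. Pairs absent from the table are treated as `"missing"`.
#'
#' @param muts data.frame with `cell_line`, `gene`, `status` (WT / mutant /
#'   missing) and optionally `protein_change`.
#' @param lines,genes optional row/column universes.
#' @return character matrix of statuses.
#' @export
mutation_status_matrix <- function(muts, lines = NULL, genes = NULL) {
  stopifnot(all(c("cell_line", "gene", "status") %in% names(muts)))
  bad <- setdiff(unique(muts$status), c("WT", "mutant", "missing"))
  if (length(bad)) stop("unknown mutation status: ", paste(bad, collapse = ", "))
  if (is.null(lines)) lines <- sort(unique(muts$cell_line))
  if (is.null(genes)) genes <- sort(unique(muts$gene))
  m <- matrix("missing", length(lines), length(genes),
              dimnames = list(lines, genes))
  keep <- muts$cell_line %in% lines & muts$gene %in% genes
  m[cbind(muts$cell_line[keep], muts$gene[keep])] <- muts$status[keep]
  m
}

# core workhorse: per gene, OLS of every feature on the mutation indicator
# (plus optional tissue dummies), returning the mutation coefficient's
# t-statistic and two-sided p for all features at once.
fit_gene_tstats <- function(v, status_mat, tissue = NULL, min_group = 3) {
  genes <- colnames(status_mat)
  feats <- colnames(v)
  tstat <- pval <- matrix(NA_real_, length(genes), length(feats),
                          dimnames = list(genes, feats))
  n_mut <- n_wt <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  skipped <- list()
  for (g in genes) {
    st <- status_mat[rownames(v), g]
    keep <- st != "missing"
    mut <- as.numeric(st[keep] == "mutant")
    nm <- sum(mut); nw <- sum(keep) - nm
    if (nm < min_group || nw < min_group) {
      skipped[[g]] <- "group_size"
      next
    }
    if (!is.null(tissue)) {
      tf <- factor(tissue[keep])
      X <- cbind(mut = mut, stats::model.matrix(~ tf))
    } else {
      X <- cbind(mut = mut, `(Intercept)` = 1)
    }
    # the mutation indicator must not lie in the span of the covariates
    q0 <- qr(X[, -1, drop = FALSE])
    if (sum(qr.resid(q0, X[, 1])^2) < 1e-8 * max(sum(X[, 1]^2), 1)) {
      skipped[[g]] <- "collinear"
      next
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      # redundancy among the covariates themselves (e.g. empty tissue level)
      X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
      qx <- qr(X)
    }
    Y <- v[keep, , drop = FALSE]
    coefs <- qr.coef(qx, Y)
    res <- Y - X %*% coefs
    df <- nrow(X) - qx$rank
    if (df < 1) {
      skipped[[g]] <- "no_residual_df"
      next
    }
    sigma2 <- colSums(res^2) / df
    mcol <- which(colnames(X) == "mut")
    xtx_inv_mm <- chol2inv(qr.R(qx))[mcol, mcol]
    se <- sqrt(pmax(sigma2 * xtx_inv_mm, .Machine$double.xmin))
    t <- coefs["mut", ] / se
    tstat[g, ] <- t
    pval[g, ] <- 2 * stats::pt(-abs(t), df)
    n_mut[g] <- nm; n_wt[g] <- nw
  }
  list(tstat = tstat, pvalue = pval, n_mut = n_mut, n_wt = n_wt,
       skipped = skipped)
}

#' Tissue-controlled mutation-metabolite association T-statistics
#'
#' For every (gene, feature) pair, fits ordinary least squares of the
#' z-scored feature on a mutation indicator plus one-hot tissue dummies (one
#' tissue dropped as reference), over the cell lines with known mutation
#' status. The mutation coefficient's T-statistic and two-sided p are
#' reported. Genes with fewer than `min_group` mutant or wild-type lines are
#' skipped, as are fits where the mutation indicator is collinear with the
#' tissue design.
#'
#' @param matrix a z-scored, cell-line-level [feature_matrix()].
#' @param muts long mutation table (see [mutation_status_matrix()]).
#' @param meta metadata mapping `cell_line` to `tissue`.
#' @param genes genes to fit; default all genes in `muts`.
#' @param min_group minimum mutant and wild-type group size.
#' @param tissue_adjust set `FALSE` to omit the tissue dummies (exposed for
#'   confounding diagnostics; the default matches the published analysis).
#' @return an `AssociationMatrix` list with `tstat`, `pvalue` (gene x
#'   feature), `n_mut`, `n_wt`, `scope` and `skipped`.
#' @export
association_tstats <- function(matrix, muts, meta, genes = NULL,
                               min_group = 3, tissue_adjust = TRUE) {
  v <- fm_values(matrix)
  lines <- rownames(v)
  if (is.null(genes)) genes <- sort(unique(muts$gene))
  status <- mutation_status_matrix(muts, lines = lines, genes = genes)
  tissue <- meta$tissue[match(lines, meta$cell_line)]
  if (anyNA(tissue)) stop("tissue missing for some cell lines")
  tiss_arg <- if (tissue_adjust && length(unique(tissue)) > 1)
    stats::setNames(tissue, lines) else NULL
  fit <- fit_gene_tstats(v, status, tissue = tiss_arg, min_group = min_group)
  structure(c(fit, list(scope = "all_tissues")), class = "AssociationMatrix")
}

#' Single-tissue association T-statistics
#'
#' Same contract as [association_tstats()] restricted to one tissue's cell
#' lines, without tissue dummies.
#'
#' @inheritParams association_tstats
#' @param tissue tissue ID present in `meta`.
#' @return an `AssociationMatrix` with `scope = tissue`.
#' @export
tissue_specific_tstats <- function(matrix, muts, meta, tissue, genes = NULL,
                                   min_group = 3) {
  tiss_of <- meta$tissue[match(rownames(matrix), meta$cell_line)]
  if (!tissue %in% tiss_of) stop("tissue not present: ", tissue)
  keep <- rownames(matrix)[tiss_of == tissue]
  v <- fm_values(matrix)[keep, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(muts$gene))
  status <- mutation_status_matrix(muts, lines = keep, genes = genes)
  fit <- fit_gene_tstats(v, status, tissue = NULL, min_group = min_group)
  structure(c(fit, list(scope = tissue)), class = "AssociationMatrix")
}

#' Cross-tissue heterogeneity of mutation signatures
#'
#' For each gene fitted in at least two tissues, the Spearman correlation
#' between its T-statistic vectors is computed for every tissue pair
#' (features missing in either member dropped pairwise) and averaged. High
#' values mean the gene's metabolic signature is tissue-agnostic.
#'
#' @param per_tissue list of `AssociationMatrix` objects (one per tissue).
#' @return data.frame with gene, mean_rho, n_tissues.
#' @export
cross_tissue_heterogeneity <- function(per_tissue) {
  if (length(per_tissue) < 2) stop("need at least 2 tissue matrices")
  genes <- sort(unique(unlist(lapply(per_tissue, function(a) rownames(a$tstat)))))
  rows <- lapply(genes, function(g) {
    vecs <- lapply(per_tissue, function(a) {
      if (g %in% rownames(a$tstat) && !all(is.na(a$tstat[g, ])))
        a$tstat[g, ] else NULL
    })
    vecs <- Filter(Negate(is.null), vecs)
    if (length(vecs) < 2) return(NULL)
    combos <- utils::combn(length(vecs), 2)
    rhos <- apply(combos, 2, function(ij) {
      a <- vecs[[ij[1]]]; b <- vecs[[ij[2]]]
      shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
      if (length(shared) < 3) return(NA_real_)
      stats::cor(a[shared], b[shared], method = "spearman")
    })
    data.frame(gene = g, mean_rho = mean(rhos, na.rm = TRUE),
               n_tissues = length(vecs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group differential metabolite analysis
#'
#' Pooled-variance two-sample T-statistic per feature, BH adjustment, and the
#' mean level (on the matrix's own scale) for the volcano x-axis.
#'
#' @param matrix a [feature_matrix()].
#' @param group_labels logical or two-level vector named by (or aligned to)
#'   the matrix rows; `TRUE` (or the second level) is the case group.
#' @param alpha significance level on the adjusted p.
#' @return data.frame with feature, tstat, p_raw, p_adjusted, mean_level,
#'   significant. The sign convention is case minus control.
#' @export
differential_metabolites <- function(matrix, group_labels, alpha = 0.05) {
  v <- fm_values(matrix)
  g <- group_labels
  if (!is.null(names(g))) g <- g[rownames(v)]
  if (!is.logical(g)) {
    f <- factor(g)
    if (nlevels(f) != 2) stop("`group_labels` must have exactly 2 levels")
    g <- f == levels(f)[2]
  }
  if (anyNA(g)) stop("group labels missing for some rows")
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 < 3 || n0 < 3) stop("need at least 3 samples per group")
  m1 <- colMeans(v[g, , drop = FALSE]); m0 <- colMeans(v[!g, , drop = FALSE])
  ss1 <- colSums(sweep(v[g, , drop = FALSE], 2, m1)^2)
  ss0 <- colSums(sweep(v[!g, , drop = FALSE], 2, m0)^2)
  df <- n1 + n0 - 2
  sp2 <- (ss1 + ss0) / df
  keep <- sp2 > 0
  if (any(!keep))
    message("skipping zero-variance features: ", sum(!keep))
  se <- sqrt(sp2[keep] * (1 / n1 + 1 / n0))
  t <- (m1[keep] - m0[keep]) / se
  p <- 2 * stats::pt(-abs(t), df)
  out <- data.frame(feature = colnames(v)[keep], tstat = t, p_raw = p,
                    p_adjusted = bh_adjust(p),
                    mean_level = colMeans(v)[keep],
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Rank genes by association with one metabolite
#'
#' @param assoc an `AssociationMatrix`.
#' @param feature feature ID.
#' @return data.frame of genes sorted by T-statistic ascending (most negative
#'   association first), ties broken by gene name.
#' @export
rank_genes_for_metabolite <- function(assoc, feature) {
  stopifnot(inherits(assoc, "AssociationMatrix"))
  if (!feature %in% colnames(assoc$tstat)) stop("feature absent: ", feature)
  t <- assoc$tstat[, feature]
  t <- t[!is.na(t)]
  ord <- order(t, names(t))
  data.frame(gene = names(t)[ord], tstat = unname(t[ord]),
             stringsAsFactors = FALSE)
}
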