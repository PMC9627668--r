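# two-sided Fisher exact p for a 2x2 table by the point-probability rule:
# sum of the probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed one.
fisher2x2_p <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("cell counts must be non-negative integers")
  K <- a + b          # row-1 margin
  n <- a + c          # column-1 margin
  N <- a + b + c + d
  support <- max(0, n - (N - K)):min(K, n)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# differential set (BH < alpha) of mutant-vs-WT lines for one gene
gene_differential_set <- function(matrix, status, alpha = 0.05) {
  lines <- rownames(matrix)
  st <- status[lines]
  keep <- !is.na(st) & st != "missing"
  g <- st[keep] == "mutant"
  sub <- fm_restage(fm_values(matrix)[lines[keep], , drop = FALSE],
                    fm_stage(matrix))
  res <- differential_metabolites(sub, stats::setNames(g, lines[keep]),
                                  alpha = alpha)
  res$feature[res$significant]
}

#' Overlap of a driver's differential metabolites with downstream genes
#'
#' The driver's differential metabolite set (mutant vs wild type, BH < alpha)
#' is intersected with the differential set of each downstream gene; the
#' shared metabolites and their percentage of the driver set quantify how
#' much of the driver's metabolic signature each downstream effector carries.
#'
#' @param matrix a z-scored cell-line-level [feature_matrix()].
#' @param muts long mutation table.
#' @param driver_gene driver gene ID.
#' @param downstream_genes character vector of downstream genes.
#' @param alpha BH significance level.
#' @return list with `driver_set` and a `table` data.frame (gene, n_shared,
#'   pct_of_driver_set, shared).
#' @export
downstream_overlap <- function(matrix, muts, driver_gene, downstream_genes,
                               alpha = 0.05) {
  status <- mutation_status_matrix(muts, lines = rownames(matrix))
  if (!driver_gene %in% colnames(status)) stop("driver gene absent")
  driver_set <- gene_differential_set(matrix, status[, driver_gene], alpha)
  note <- NULL
  if (!length(driver_set)) note <- "empty driver differential set"
  rows <- lapply(downstream_genes, function(g) {
    if (!g %in% colnames(status)) stop("downstream gene absent: ", g)
    gset <- gene_differential_set(matrix, status[, g], alpha)
    shared <- intersect(driver_set, gset)
    data.frame(gene = g, n_shared = length(shared),
               pct_of_driver_set = if (length(driver_set))
                 100 * length(shared) / length(driver_set) else 0,
               shared = I(list(shared)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(driver_set = driver_set, table = out, note = note)
}

#' Mutation-class pathway associations (Fisher's exact test)
#'
#' Cell lines mutant for `gene` are split into classes by their recorded
#' protein change (e.g. DNA-contact vs conformation mutations of TP53);
#' unclassified mutants are excluded. Per class, the differential metabolite
#' set against wild-type lines is computed, and each pathway is tested with
#' a two-sided Fisher exact test on the 2x2 table (differential vs not,
#' pathway member vs not) over the measured universe, BH-adjusted across
#' all (class, pathway) tests.
#'
#' @param matrix a z-scored cell-line-level [feature_matrix()].
#' @param muts long mutation table with `protein_change` on mutant rows.
#' @param gene the mutated gene.
#' @param class_map data.frame with `protein_change`, `class`.
#' @param db a [pathway_db()] over the metabolite features.
#' @param alpha BH level for the per-class differential sets.
#' @return data.frame with class, pathway, n_diff, n_members, n_overlap,
#'   p_raw, p_adjusted.
#' @export
class_pathway_association <- function(matrix, muts, gene, class_map, db,
                                      alpha = 0.05) {
  stopifnot(inherits(db, "PathwayDB"))
  lines <- rownames(matrix)
  gm <- muts[muts$gene == gene & muts$cell_line %in% lines, , drop = FALSE]
  if (!nrow(gm)) stop("gene absent from mutation table: ", gene)
  status <- stats::setNames(gm$status, gm$cell_line)
  cls <- rep(NA_character_, nrow(gm))
  if ("protein_change" %in% names(gm)) {
    hit <- match(gm$protein_change, class_map$protein_change)
    cls <- class_map$class[hit]
  }
  cls[gm$status != "mutant"] <- NA
  class_of <- stats::setNames(cls, gm$cell_line)
  wt_lines <- names(status)[status == "WT"]
  if (length(wt_lines) < 3) stop("need at least 3 wild-type lines")
  universe <- colnames(matrix)
  rows <- list()
  for (cl in sort(unique(stats::na.omit(cls)))) {
    cl_lines <- names(class_of)[!is.na(class_of) & class_of == cl]
    if (length(cl_lines) < 3) {
      message("skipping class with < 3 lines: ", cl)
      next
    }
    keep <- c(wt_lines, cl_lines)
    g <- stats::setNames(rownames(matrix) %in% cl_lines, rownames(matrix))[keep]
    sub <- fm_restage(fm_values(matrix)[keep, , drop = FALSE],
                      fm_stage(matrix))
    diff_res <- differential_metabolites(sub, g, alpha = alpha)
    diff_set <- diff_res$feature[diff_res$significant]
    for (pw in names(db$pathways)) {
      memb <- intersect(db$pathways[[pw]], universe)
      if (!length(memb)) next
      a <- length(intersect(diff_set, memb))
      b <- length(diff_set) - a
      c_ <- length(memb) - a
      d <- length(universe) - a - b - c_
      rows[[paste(cl, pw)]] <- data.frame(
        class = cl, pathway = pw, n_diff = length(diff_set),
        n_members = length(memb), n_overlap = a,
        p_raw = if (length(diff_set)) fisher2x2_p(a, b, c_, d) else 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no class with enough lines")
  out$p_adjusted <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Pathway similarity tree
#'
#' Average-linkage hierarchical clustering of pathways on the distance
#' `1 - Pearson r` between their rank-sum-change vectors across cell lines,
#' emitted as a Newick string with branch lengths derived from the merge
#' heights. Constant pathway vectors are dropped; column order (hence
#' tie-breaking) is fixed by pathway name.
#'
#' @param activity an `ActivityMatrix` from [pathway_activity()].
#' @return a Newick string.
#' @export
pathway_similarity_tree <- function(activity) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  rsc <- activity$rank_sum_change
  rsc <- rsc[, order(colnames(rsc)), drop = FALSE]
  sds <- apply(rsc, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping constant pathways: ",
            paste(colnames(rsc)[sds == 0], collapse = ", "))
    rsc <- rsc[, sds > 0, drop = FALSE]
  }
  if (ncol(rsc) < 3) stop("need at least 3 variable pathways")
  d <- stats::as.dist(1 - stats::cor(rsc))
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
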