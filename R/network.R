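#' Build a thresholded gene-metabolite correlation graph
#'
#' Computes Pearson correlations for every pair of genes, metabolites and
#' gene-metabolites over the shared cell lines and links pairs whose
#' correlation exceeds the threshold. The published rule links on signed
#' `r > threshold`; set `absolute = TRUE` to link on `|r|`. Expression
#' values are log-transformed with a +1 offset; the metabolite matrix is
#' used on its own scale (typically z-scored or cell-line averages).
#'
#' @param expr cell line x gene numeric matrix.
#' @param metab a cell-line-level [feature_matrix()].
#' @param threshold correlation cutoff in (0, 1).
#' @param absolute link on `|r|` instead of signed r.
#' @param log_expr log1p-transform the expression matrix first.
#' @return a `CorrelationGraph` list with `nodes` (id, type), `edges`
#'   (a, b, r), `threshold`, `absolute`.
#' @export
build_correlation_graph <- function(expr, metab, threshold = 0.8,
                                    absolute = FALSE, log_expr = TRUE) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  expr <- as.matrix(expr)
  mv <- fm_values(metab)
  shared <- intersect(rownames(expr), rownames(mv))
  if (length(shared) < 5) stop("need at least 5 shared cell lines")
  E <- expr[shared, , drop = FALSE]
  if (log_expr) E <- log1p(E)
  M <- mv[shared, , drop = FALSE]
  dup <- intersect(colnames(E), colnames(M))
  if (length(dup)) stop("gene and metabolite IDs overlap: ", dup[1])
  X <- cbind(E, M)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping zero-variance columns: ", sum(sds == 0))
    X <- X[, sds > 0, drop = FALSE]
  }
  type <- ifelse(colnames(X) %in% colnames(E), "gene", "metabolite")
  C <- stats::cor(X)
  crit <- if (absolute) abs(C) else C
  crit[lower.tri(crit, diag = TRUE)] <- -Inf
  hits <- which(crit > threshold, arr.ind = TRUE)
  edges <- data.frame(a = colnames(X)[hits[, 1]], b = colnames(X)[hits[, 2]],
                      r = C[hits], stringsAsFactors = FALSE)
  structure(list(nodes = data.frame(id = colnames(X), type = type,
                                    stringsAsFactors = FALSE),
                 edges = edges, threshold = threshold, absolute = absolute),
            class = "CorrelationGraph")
}

#' @export
print.CorrelationGraph <- function(x, ...) {
  cat(sprintf("CorrelationGraph: %d nodes (%d genes, %d metabolites), %d edges at r > %.2f%s\n",
              nrow(x$nodes), sum(x$nodes$type == "gene"),
              sum(x$nodes$type == "metabolite"), nrow(x$edges), x$threshold,
              if (x$absolute) " (absolute)" else ""))
  invisible(x)
}

#' Size-filtered connected components
#'
#' Connected components of the undirected correlation graph with at least
#' `min_size` members, sorted by size descending. (On an undirected graph,
#' "strongly connected" degenerates to plain connectedness.)
#'
#' @param graph a `CorrelationGraph`.
#' @param min_size minimum component size.
#' @return list of character vectors of node IDs (possibly empty).
#' @export
graph_components <- function(graph, min_size = 10) {
  stopifnot(inherits(graph, "CorrelationGraph"))
  g <- igraph::graph_from_data_frame(graph$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = graph$nodes$id)
  comp <- igraph::components(g)
  sets <- split(names(comp$membership), comp$membership)
  sets <- sets[lengths(sets) >= min_size]
  sets <- sets[order(-lengths(sets))]
  unname(lapply(sets, sort))
}

#' Over-representation analysis of one component
#'
#' The component's metabolite members are tested against the metabolite
#' database and its gene members against the gene database, each with the
#' graph's same-typed node set as universe.
#'
#' @param component character vector of node IDs.
#' @param graph the `CorrelationGraph` the component came from (defines the
#'   universes).
#' @param metab_db,gene_db [pathway_db()] objects (either may be `NULL`).
#' @return list with `metabolite` and `gene` ORA tables (`NULL` where the
#'   typed subset or database is empty, with a `note`).
#' @export
component_ora <- function(component, graph, metab_db = NULL, gene_db = NULL) {
  stopifnot(inherits(graph, "CorrelationGraph"))
  typed <- split(graph$nodes$id, graph$nodes$type)
  run_side <- function(db, type) {
    sel <- intersect(component, typed[[type]])
    if (is.null(db) || !length(sel))
      return(list(result = NULL,
                  note = sprintf("no %s members or no database", type)))
    list(result = ora(sel, db, universe = typed[[type]]), note = NULL)
  }
  metab <- run_side(metab_db, "metabolite")
  gene <- run_side(gene_db, "gene")
  list(metabolite = metab$result, metabolite_note = metab$note,
       gene = gene$result, gene_note = gene$note)
}
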