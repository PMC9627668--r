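#' Pathway database
#'
#' Named feature (metabolite or gene) sets together with the universe they are
#' drawn from, in the spirit of SMPDB/KEGG set collections exchanged as GMT.
#'
#' @param pathways named list of character vectors (member IDs). Names must be
#'   unique, sets non-empty; duplicate members within a set are removed with a
#'   warning.
#' @param universe character vector of all possible member IDs. Every pathway
#'   member must belong to it.
#' @return a `PathwayDB` object (list with elements `pathways`, `universe`).
#' @export
pathway_db <- function(pathways, universe) {
  if (!is.list(pathways) || is.null(names(pathways)) ||
      anyDuplicated(names(pathways)) || any(names(pathways) == ""))
    stop("`pathways` must be a named list with unique non-empty names")
  if (!length(universe)) stop("`universe` must be non-empty")
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("`universe` has duplicated IDs")
  pathways <- lapply(pathways, function(m) {
    m <- as.character(m)
    if (anyDuplicated(m)) {
      warning("duplicated members within a pathway removed")
      m <- unique(m)
    }
    m
  })
  if (any(lengths(pathways) == 0)) stop("empty pathway set")
  stray <- setdiff(unique(unlist(pathways)), universe)
  if (length(stray))
    stop("pathway members outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(pathways = pathways, universe = universe),
            class = "PathwayDB")
}

#' @export
print.PathwayDB <- function(x, ...) {
  cat(sprintf("PathwayDB: %d pathways over a universe of %d IDs\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Read a GMT file into a PathwayDB
#'
#' GMT is tab-separated: name, description, then member IDs. The universe
#' defaults to the union of all members unless supplied.
#'
#' @param path file path.
#' @param universe optional universe; defaults to the union of members.
#' @return a [pathway_db()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", bad[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate pathway names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  pathway_db(sets, universe)
}

#' Write a PathwayDB as GMT
#'
#' @param db a [pathway_db()].
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  stopifnot(inherits(db, "PathwayDB"))
  nm <- names(db$pathways)
  desc <- rep("na", length(nm))
  if (!is.null(descriptions)) {
    hit <- match(nm, names(descriptions))
    desc[!is.na(hit)] <- descriptions[hit[!is.na(hit)]]
  }
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], db$pathways[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
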