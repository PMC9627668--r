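# ---- TSV / JSON artifact I/O -------------------------------------------
# All tabular artifacts are TSV, UTF-8, samples as rows, missing values as
# empty cells, with a single `#`-prefixed schema-version header line.

schema_header <- function(kind) sprintf("# metaboline %s v1", kind)

write_tsv_artifact <- function(df, path, kind) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(schema_header(kind), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv_artifact <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a FeatureMatrix as TSV
#'
#' Rows are samples, the first column is `sample_id`, remaining columns are
#' features. The processing stage is recorded in the schema header.
#'
#' @param matrix a [feature_matrix()].
#' @param path file path.
#' @return `path` (write) or a [feature_matrix()] (read), with the stage
#'   recovered from the header.
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  df <- data.frame(sample_id = rownames(matrix), fm_values(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_artifact(df, path, paste0("feature_matrix stage=", fm_stage(matrix)))
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  first <- readLines(path, n = 1)
  stage <- sub(".*stage=(\\S+).*", "\\1", first)
  if (identical(stage, first)) stage <- "raw"
  df <- read_tsv_artifact(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_matrix(m, stage = stage)
}

#' Write / read sample metadata
#' @param meta metadata data.frame with `sample_id` first.
#' @param path file path.
#' @export
write_sample_meta <- function(meta, path) {
  write_tsv_artifact(meta, path, "sample_meta")
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) read_tsv_artifact(path)

#' Write / read a long mutation table
#' @param muts data.frame (cell_line, gene, status, ...).
#' @param path file path.
#' @export
write_mutation_table <- function(muts, path) {
  write_tsv_artifact(muts, path, "mutations")
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) read_tsv_artifact(path)

#' Write / read a cell-line by column numeric table (scores, drugs)
#' @param x numeric matrix with cell-line row names.
#' @param path file path.
#' @param kind schema label.
#' @export
write_score_table <- function(x, path, kind = "scores") {
  df <- data.frame(cell_line = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_artifact(df, path, kind)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read_tsv_artifact(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# ---- pipeline orchestration --------------------------------------------

default_pipeline_params <- function() {
  list(drift_span = 0.3, confluency_span = 0.5, threshold_log2_sum = 25,
       max_remove = 50, alpha = 0.05, min_frac_significant = 0.40,
       rank_sum_threshold = 350, min_group = 3, n_perm = 2000,
       network_threshold = 0.8, min_component_size = 10)
}

#' Run the pipeline end to end
#'
#' Executes the fixed stage order qc (drift, low-intensity, confluency,
#' batch/plate filter) -> z-score -> replicate averaging -> pathway activity
#' -> mutation association -> score/drug enrichment -> tissue-clustering
#' permutation test, writing every intermediate artifact and a manifest
#' (parameters, seeds, file checksums) under `outdir`. Inputs may come from
#' files or from the synthetic generator (`config$simulate`). Input files
#' are never modified.
#'
#' @param config list with `seed`, `outdir`, and either `simulate` (a list
#'   with optional `study`, `pathways`, `effects`, `couplings` entries) or
#'   `inputs` (paths: `matrix`, `meta`, and optionally `gmt`, `mutations`,
#'   `scores`, `drugs`, `synergy`); optional `params` overrides
#'   `default_pipeline_params()`.
#' @return the manifest list, invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config error: `seed` is required")
  if (is.null(config$outdir)) stop("config error: `outdir` is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- list(stage = stage, message = msg)
  }
  artifacts <- character(0)
  save_tsv <- function(obj, name, writer) {
    path <- file.path(outdir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
    path
  }

  # --- inputs -----------------------------------------------------------
  muts <- scores <- drugs <- synergy <- db <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    study_args <- utils::modifyList(list(seed = config$seed),
                                    sim$study %||% list())
    cfg <- do.call(study_config, study_args)
    st <- generate_study(cfg)
    mat <- st$matrix; meta <- st$meta; truth <- st$truth
    pw <- utils::modifyList(list(n_pathways = 15, size_min = 5, size_max = 15),
                            sim$pathways %||% list())
    db <- generate_pathways(pw$n_pathways, c(pw$size_min, pw$size_max),
                            colnames(mat), seed = config$seed + 1)
    if (!is.null(sim$effects)) {
      pl <- plant_mutation_effects(mat, meta, sim$effects,
                                   seed = config$seed + 2)
      mat <- pl$matrix; muts <- pl$mutations
      truth$planted_gene_effects <- pl$truth$planted_gene_effects
    }
    save_tsv(mat, "matrix_raw.tsv", write_feature_matrix)
    save_tsv(meta, "sample_meta.tsv", write_sample_meta)
    save_tsv(db, "pathways.gmt", write_gmt)
    if (!is.null(muts)) save_tsv(muts, "mutations.tsv", write_mutation_table)
    truth_path <- file.path(outdir, "ground_truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    artifacts <- c(artifacts, truth_path)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (req in c("matrix", "meta"))
      if (is.null(inp[[req]]) || !file.exists(inp[[req]]))
        stop("config error: missing input file for `", req, "`")
    for (opt in c("gmt", "mutations", "scores", "drugs", "synergy"))
      if (!is.null(inp[[opt]]) && !file.exists(inp[[opt]]))
        stop("config error: input file not found: ", inp[[opt]])
    mat <- read_feature_matrix(inp$matrix)
    meta <- read_sample_meta(inp$meta)
    if (!is.null(inp$gmt)) db <- read_gmt(inp$gmt)
    if (!is.null(inp$mutations)) muts <- read_mutation_table(inp$mutations)
    if (!is.null(inp$scores)) scores <- read_score_table(inp$scores)
    if (!is.null(inp$drugs)) drugs <- read_score_table(inp$drugs)
    if (!is.null(inp$synergy)) synergy <- read_tsv_artifact(inp$synergy)
  } else stop("config error: provide either `simulate` or `inputs`")

  if (!is.null(config$simulate) && !is.null(config$simulate$couplings)) {
    # couplings need the cell-line matrix; generated after averaging below
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- qc ----------------------------------------------------------------
  qc <- run_stage("qc", {
    auc_raw_bio <- replicate_roc_auc(mat, meta, "biological")
    auc_raw_tech <- replicate_roc_auc(mat, meta, "technical")
    m1 <- correct_injection_drift(mat, meta, span = params$drift_span)
    low <- drop_low_intensity_injections(m1, params$threshold_log2_sum)
    if (length(low$removed)) note("qc", paste("removed_low_intensity:",
                                              paste(low$removed, collapse = ",")))
    m2 <- correct_confluency(low$matrix, meta, span = params$confluency_span)
    bf <- batch_plate_filter(m2, meta, max_remove = params$max_remove)
    if (length(bf$report$removed_features))
      note("qc", paste("removed_batch_features:",
                       paste(bf$report$removed_features, collapse = ",")))
    bf$report$removed_injections <- low$removed
    bf$report$auc_raw_biological <- auc_raw_bio
    bf$report$auc_raw_technical <- auc_raw_tech
    bf
  })
  save_tsv(qc$matrix, "matrix_qc.tsv", write_feature_matrix)

  zs <- run_stage("zscore", zscore_features(qc$matrix))
  avg <- run_stage("average", average_biological_replicates(zs, meta))
  # rank-based activity needs the bulk abundance ordering, so it gets the
  # replicate-averaged log10 intensities rather than z-scores
  avg_int <- run_stage("average",
                       average_biological_replicates(qc$matrix, meta,
                                                     log10 = TRUE))
  save_tsv(avg, "matrix_cellline.tsv", write_feature_matrix)
  save_tsv(avg_int, "matrix_cellline_log10.tsv", write_feature_matrix)

  # synthetic couplings are generated from the final cell-line matrix
  if (!is.null(config$simulate) && !is.null(config$simulate$couplings)) {
    cpl <- config$simulate$couplings
    if (!is.data.frame(cpl)) cpl <- do.call(rbind, lapply(cpl, as.data.frame))
    sd_out <- generate_scores_and_drugs(avg, db, cpl, seed = config$seed + 3)
    scores <- sd_out$scores; drugs <- sd_out$drugs; synergy <- sd_out$synergy
    save_tsv(scores, "scores.tsv", write_score_table)
    save_tsv(drugs, "drugs.tsv",
             function(x, p) write_score_table(x, p, kind = "drugs_ln_ic50"))
    save_tsv(synergy, "synergy.tsv",
             function(x, p) write_tsv_artifact(x, p, "synergy"))
  }

  results <- list(qc_report = qc$report[c("auc_raw_biological",
                                          "auc_raw_technical",
                                          "auc_biological", "auc_technical",
                                          "removed_injections",
                                          "removed_features")])

  if (!is.null(db)) {
    act <- run_stage("activity", pathway_activity(
      avg_int, db, alpha = params$alpha,
      min_frac_significant = params$min_frac_significant,
      rank_sum_threshold = params$rank_sum_threshold))
    save_tsv(data.frame(cell_line = rownames(act$rank_sum_change),
                        act$rank_sum_change, check.names = FALSE),
             "pathway_rank_sum_change.tsv",
             function(x, p) write_tsv_artifact(x, p, "activity_rank_sum"))
    results$activity_flagged <- act$flagged
    if (!all(is.na(meta$doubling_time))) {
      dtr <- run_stage("activity", doubling_time_regression(act, meta))
      save_tsv(dtr, "doubling_time_regression.tsv",
               function(x, p) write_tsv_artifact(x, p, "doubling_time"))
    }
    if (ncol(act$rank_sum_change) >= 3) {
      nw <- run_stage("subtype", pathway_similarity_tree(act))
      tree_path <- file.path(outdir, "pathway_tree.nwk")
      writeLines(nw, tree_path)
      artifacts <- c(artifacts, tree_path)
    }
  }

  if (!is.null(muts)) {
    assoc <- run_stage("association", association_tstats(
      avg, muts, meta, min_group = params$min_group))
    save_tsv(data.frame(gene = rownames(assoc$tstat), assoc$tstat,
                        check.names = FALSE),
             "association_tstats.tsv",
             function(x, p) write_tsv_artifact(x, p, "association_tstats"))
    results$association_skipped <- assoc$skipped
  }

  if (!is.null(scores) && !is.null(db)) {
    enr <- run_stage("enrichment", {
      do.call(rbind, lapply(colnames(scores), function(sn) {
        r <- metabolite_score_correlation(avg, scores, sn)
        cbind(score = sn, pathway_score_enrichment(r, db))
      }))
    })
    save_tsv(enr, "score_pathway_enrichment.tsv",
             function(x, p) write_tsv_artifact(x, p, "score_enrichment"))
  }

  if (!is.null(drugs) && !is.null(db)) {
    dpp <- run_stage("drugs", drug_pathway_profiles(avg, drugs, db))
    save_tsv(data.frame(drug = rownames(dpp$signed_stat), dpp$signed_stat,
                        check.names = FALSE),
             "drug_pathway_signed_stat.tsv",
             function(x, p) write_tsv_artifact(x, p, "drug_profiles"))
    if (nrow(dpp$signed_stat) >= 2 && ncol(dpp$signed_stat) >= 3) {
      anti <- run_stage("drugs", drug_pair_anticorrelation(dpp))
      save_tsv(anti$pairs, "drug_pair_anticorrelation.tsv",
               function(x, p) write_tsv_artifact(x, p, "drug_pairs"))
      if (!is.null(synergy) && nrow(synergy)) {
        ov <- tryCatch(synergy_overlay(anti, synergy, n_perm = params$n_perm,
                                       seed = config$seed + 4),
                       error = function(e) {
                         note("drugs", conditionMessage(e)); NULL
                       })
        if (!is.null(ov)) {
          tab <- ov$table
          tab$enrichment_p <- ov$enrichment$p
          save_tsv(tab, "synergy_overlay.tsv",
                   function(x, p) write_tsv_artifact(x, p, "synergy_overlay"))
        }
      }
    }
  }

  ptest <- run_stage("permutation", {
    hc <- stats::hclust(stats::dist(fm_values(avg)), method = "average")
    leaves <- rownames(avg)[hc$order]
    tiss <- meta$tissue[match(leaves, meta$cell_line)]
    permutation_pvalue(tiss, n_perm = params$n_perm, seed = config$seed + 5)
  })
  results$tissue_clustering <- list(observed = ptest$observed, p = ptest$p,
                                    n_perm = ptest$n_perm,
                                    exhaustive = ptest$exhaustive)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metaboline")),
    seed = config$seed, params = params, results = results, log = log,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- command-line interface --------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1]
      i <- i + 2L
    }
  }
  flags
}

read_cli_config <- function(flags) {
  if (is.null(flags$config)) return(list())
  jsonlite::read_json(flags$config, simplifyVector = TRUE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (synthetic study to TSV/GMT/JSON), `run` (full
#' pipeline from a JSON config or simulated defaults), `qc`, `activity`,
#' `associate`, `enrich`, `drugs`, `network`, `subtype`, `permtest`. Global
#' flags: `--seed`, `--config`, `--outdir` plus per-command input paths
#' (`--matrix`, `--meta`, `--gmt`, `--mutations`, `--scores`, `--drugs`,
#' `--expr`, ...). Invoked by the installed script
#' `system.file("cli", "metaboline.R", package = "metaboline")`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status 0, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: metaboline <command> [--flags]")
  command <- args[1]
  flags <- parse_cli_flags(args[-1])
  seed <- as.integer(flags$seed %||% 1)
  outdir <- flags$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- read_cli_config(flags)

  need <- function(...) {
    for (k in c(...)) if (is.null(flags[[k]]))
      stop("missing required flag --", k, " for command ", command)
  }
  load_mm <- function() {
    need("matrix", "meta")
    list(mat = read_feature_matrix(flags$matrix),
         meta = read_sample_meta(flags$meta))
  }

  switch(command,
    simulate = {
      run_cfg <- list(seed = seed, outdir = outdir,
                      simulate = cfg$simulate %||% list(),
                      params = cfg$params %||% list())
      # simulate-only: emit the inputs, then stop before analysis by using
      # the generator directly
      sim <- run_cfg$simulate
      study_args <- utils::modifyList(list(seed = seed), sim$study %||% list())
      st <- generate_study(do.call(study_config, study_args))
      write_feature_matrix(st$matrix, file.path(outdir, "matrix_raw.tsv"))
      write_sample_meta(st$meta, file.path(outdir, "sample_meta.tsv"))
      pw <- utils::modifyList(list(n_pathways = 15, size_min = 5,
                                   size_max = 15), sim$pathways %||% list())
      db <- generate_pathways(pw$n_pathways, c(pw$size_min, pw$size_max),
                              colnames(st$matrix), seed = seed + 1)
      write_gmt(db, file.path(outdir, "pathways.gmt"))
      jsonlite::write_json(st$truth, file.path(outdir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    },
    run = {
      run_cfg <- c(list(seed = seed, outdir = outdir), cfg)
      if (is.null(run_cfg$simulate) && is.null(run_cfg$inputs))
        run_cfg$simulate <- list()
      run_pipeline(run_cfg)
    },
    qc = {
      x <- load_mm()
      cfgp <- utils::modifyList(default_pipeline_params(), cfg$params %||% list())
      m1 <- correct_injection_drift(x$mat, x$meta, span = cfgp$drift_span)
      low <- drop_low_intensity_injections(m1, cfgp$threshold_log2_sum)
      m2 <- correct_confluency(low$matrix, x$meta, span = cfgp$confluency_span)
      bf <- batch_plate_filter(m2, x$meta, max_remove = cfgp$max_remove)
      write_feature_matrix(bf$matrix, file.path(outdir, "matrix_qc.tsv"))
      avg <- average_biological_replicates(zscore_features(bf$matrix), x$meta)
      write_feature_matrix(avg, file.path(outdir, "matrix_cellline.tsv"))
      avg_int <- average_biological_replicates(bf$matrix, x$meta, log10 = TRUE)
      write_feature_matrix(avg_int,
                           file.path(outdir, "matrix_cellline_log10.tsv"))
      jsonlite::write_json(bf$report[c("auc_biological", "auc_technical",
                                       "removed_features")],
                           file.path(outdir, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    },
    activity = {
      need("matrix", "gmt")
      mat <- read_feature_matrix(flags$matrix)
      db <- read_gmt(flags$gmt)
      act <- pathway_activity(mat, db)
      write_tsv_artifact(data.frame(cell_line = rownames(act$rank_sum_change),
                                    act$rank_sum_change, check.names = FALSE),
                         file.path(outdir, "pathway_rank_sum_change.tsv"),
                         "activity_rank_sum")
    },
    associate = {
      need("matrix", "meta", "mutations")
      mat <- read_feature_matrix(flags$matrix)
      meta <- read_sample_meta(flags$meta)
      muts <- read_mutation_table(flags$mutations)
      assoc <- association_tstats(mat, muts, meta)
      write_tsv_artifact(data.frame(gene = rownames(assoc$tstat), assoc$tstat,
                                    check.names = FALSE),
                         file.path(outdir, "association_tstats.tsv"),
                         "association_tstats")
    },
    enrich = {
      need("matrix", "scores", "gmt")
      mat <- read_feature_matrix(flags$matrix)
      sc <- read_score_table(flags$scores)
      db <- read_gmt(flags$gmt)
      out <- do.call(rbind, lapply(colnames(sc), function(sn) {
        r <- metabolite_score_correlation(mat, sc, sn)
        cbind(score = sn, pathway_score_enrichment(r, db))
      }))
      write_tsv_artifact(out, file.path(outdir, "score_pathway_enrichment.tsv"),
                         "score_enrichment")
    },
    drugs = {
      need("matrix", "drugs", "gmt")
      mat <- read_feature_matrix(flags$matrix)
      dr <- read_score_table(flags$drugs)
      db <- read_gmt(flags$gmt)
      dpp <- drug_pathway_profiles(mat, dr, db)
      write_tsv_artifact(data.frame(drug = rownames(dpp$signed_stat),
                                    dpp$signed_stat, check.names = FALSE),
                         file.path(outdir, "drug_pathway_signed_stat.tsv"),
                         "drug_profiles")
      anti <- drug_pair_anticorrelation(dpp)
      write_tsv_artifact(anti$pairs,
                         file.path(outdir, "drug_pair_anticorrelation.tsv"),
                         "drug_pairs")
    },
    network = {
      need("matrix", "expr")
      mat <- read_feature_matrix(flags$matrix)
      expr <- read_score_table(flags$expr)
      thr <- as.numeric(flags$threshold %||% 0.8)
      gr <- build_correlation_graph(expr, mat, threshold = thr,
                                    absolute = isTRUE(flags$absolute))
      write_tsv_artifact(gr$edges, file.path(outdir, "network_edges.tsv"),
                         "network_edges")
      comps <- graph_components(gr, min_size = as.integer(flags$`min-size` %||% 10))
      comp_df <- data.frame(
        component = rep(seq_along(comps), lengths(comps)),
        id = unlist(comps),
        stringsAsFactors = FALSE)
      write_tsv_artifact(comp_df, file.path(outdir, "network_components.tsv"),
                         "network_components")
    },
    subtype = {
      need("matrix", "mutations", "gene", "classes", "gmt")
      mat <- read_feature_matrix(flags$matrix)
      muts <- read_mutation_table(flags$mutations)
      class_map <- read_tsv_artifact(flags$classes)
      db <- read_gmt(flags$gmt)
      out <- class_pathway_association(mat, muts, flags$gene, class_map, db)
      write_tsv_artifact(out, file.path(outdir, "class_pathway_association.tsv"),
                         "class_association")
    },
    permtest = {
      need("matrix", "meta")
      mat <- read_feature_matrix(flags$matrix)
      meta <- read_sample_meta(flags$meta)
      hc <- stats::hclust(stats::dist(fm_values(mat)), method = "average")
      leaves <- rownames(mat)[hc$order]
      tiss <- meta$tissue[match(leaves, meta$cell_line)]
      res <- permutation_pvalue(tiss, n_perm = as.integer(flags$`n-perm` %||% 10000),
                                seed = seed)
      jsonlite::write_json(res[c("observed", "p", "n_perm", "exhaustive")],
                           file.path(outdir, "tissue_clustering.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    },
    stop("unknown command: ", command)
  )
  invisible(0L)
}
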