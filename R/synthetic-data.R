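#' Configuration for a synthetic cell-line metabolomics study
#'
#' The generator emulates the statistical structure of a replicate-structured
#' cell-line panel: three biological and two technical replicates per line,
#' several tissues, lognormal baseline intensities, a smooth injection-order
#' drift shared across features, a monotone confluency scaling of total
#' intensity, and batch/plate offsets restricted to a feature subset. All log
#' SDs are on the natural-log intensity scale. The default ordering
#' `noise_sd_tech < noise_sd_bio < between_line_sd` reproduces the replicate
#' ROC structure (technical AUC > biological AUC > 0.5).
#'
#' @param n_cell_lines,n_tissues,n_bio_reps,n_tech_reps,n_features positive
#'   integers describing the design.
#' @param seed non-negative integer; mandatory, every downstream draw is
#'   derived from it.
#' @param noise_sd_tech,noise_sd_bio,between_line_sd,tissue_sd log-scale SDs of
#'   technical noise, biological (culture) noise, cell-line effects and
#'   tissue effects.
#' @param baseline_log_mean,baseline_log_sd lognormal baseline of feature
#'   intensities (natural-log scale). By default `baseline_log_mean` is set
#'   from the panel size so that per-sample log2 total intensity sits near
#'   26 regardless of `n_features` (the total ion current is an instrument
#'   property, not a panel-size one), just above the low-intensity cutoff
#'   of 25.
#' @param drift_amplitude amplitude (log units) of the shared injection-order
#'   drift (linear trend plus low-frequency sinusoid), scaled per feature by a
#'   Uniform(0.5, 1.5) factor.
#' @param confluency_effect multiplicative log-scale coefficient of centred
#'   confluency on every feature of a sample.
#' @param bio_outlier_frac,bio_outlier_mult fraction of cultures whose
#'   biological noise SD is inflated by `bio_outlier_mult` (divergent
#'   cultures: passage drift, stress). These outliers are what keeps the
#'   biological replicate AUC below its combinatorial ceiling, as observed
#'   in real panels; technical replicates share the culture state and are
#'   unaffected.
#' @param n_latent_factors,latent_frac cell-line effects are built from
#'   `n_latent_factors` shared latent programs carrying `latent_frac` of the
#'   between-line variance (the rest is feature-independent). This emulates
#'   co-regulated metabolite programs and is what keeps the biological
#'   replicate AUC below its combinatorial ceiling, as in real panels.
#' @param batch_frac fraction of features receiving batch/plate offsets.
#' @param batch_effect_sd SD of the per-(batch, feature) log offsets.
#' @param n_batches,n_plates number of injection-order batches and plates.
#' @return a validated `StudyConfig` list.
#' @export
study_config <- function(n_cell_lines = 20, n_tissues = 4,
                         n_bio_reps = 3, n_tech_reps = 2,
                         n_features = 300, seed = NULL,
                         noise_sd_tech = 0.05, noise_sd_bio = 0.15,
                         between_line_sd = 0.5, tissue_sd = 0.3,
                         n_latent_factors = 4, latent_frac = 0.6,
                         bio_outlier_frac = 0.08, bio_outlier_mult = 5,
                         baseline_log_mean = NULL, baseline_log_sd = 1,
                         drift_amplitude = 0.8, confluency_effect = 1.0,
                         batch_frac = 0.1, batch_effect_sd = 0.5,
                         n_batches = 4, n_plates = 8) {
  if (is.null(seed)) stop("`seed` is mandatory: reproducibility is required")
  dims <- c(n_cell_lines = n_cell_lines, n_tissues = n_tissues,
            n_bio_reps = n_bio_reps, n_tech_reps = n_tech_reps,
            n_features = n_features, n_batches = n_batches,
            n_plates = n_plates)
  if (any(dims < 1) || any(dims != floor(dims)))
    stop("design dimensions must be positive integers")
  if (n_tissues > n_cell_lines) stop("more tissues than cell lines")
  sds <- c(noise_sd_tech, noise_sd_bio, between_line_sd, tissue_sd,
           baseline_log_sd, drift_amplitude, confluency_effect,
           batch_effect_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("SDs and amplitudes must be finite and non-negative")
  if (is.null(baseline_log_mean))
    baseline_log_mean <- log(2^26) - log(n_features) - baseline_log_sd^2 / 2
  if (batch_frac < 0 || batch_frac > 1) stop("`batch_frac` must be in [0,1]")
  if (latent_frac < 0 || latent_frac > 1) stop("`latent_frac` must be in [0,1]")
  if (n_latent_factors < 1 || n_latent_factors != floor(n_latent_factors))
    stop("`n_latent_factors` must be a positive integer")
  if (any(c(noise_sd_tech, noise_sd_bio, between_line_sd) > 0) &&
      !(noise_sd_tech <= noise_sd_bio && noise_sd_bio <= between_line_sd))
    warning("SD ordering noise_sd_tech <= noise_sd_bio <= between_line_sd ",
            "is violated; replicate ROC ordering may not hold")
  cfg <- as.list(environment())
  cfg$dims <- NULL
  cfg$sds <- NULL
  structure(cfg, class = "StudyConfig")
}

# shared drift shape on a 0..1 injection axis: linear trend plus 1.5 periods
# of a sinusoid (orthogonal to the linear term, so Lowess has real work to do)
drift_shape <- function(frac) (frac - 0.5) + 0.3 * sin(3 * pi * frac)

#' Generate a synthetic study
#'
#' Draws one sample row per (cell line, biological replicate, technical
#' replicate). On the natural-log scale each intensity is the sum of a feature
#' baseline, a tissue effect, a cell-line effect, biological and technical
#' noise, the shared injection drift, a confluency term, and (for the batch
#' feature subset) a batch plus plate offset; values are then exponentiated.
#' Injection indices are a random permutation of `1:n_samples`; confluency is
#' Uniform(0.3, 1); batches and plates are contiguous injection blocks.
#' Identical configs give bit-identical output.
#'
#' @param config a [study_config()].
#' @return list with `matrix` (a raw-stage [feature_matrix()]), `meta`
#'   (sample metadata data.frame) and `truth` (ground-truth record of every
#'   planted component).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  withr::with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  nl <- cfg$n_cell_lines; nb <- cfg$n_bio_reps; nt <- cfg$n_tech_reps
  nf <- cfg$n_features
  n <- nl * nb * nt
  lines <- sprintf("CL%03d", seq_len(nl))
  feats <- sprintf("M%04d", seq_len(nf))
  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  tissue_of <- stats::setNames(tissues[(seq_len(nl) - 1L) %% cfg$n_tissues + 1L],
                               lines)

  meta <- expand.grid(tech_rep = seq_len(nt), bio_rep = seq_len(nb),
                      cell_line = lines, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("cell_line", "bio_rep", "tech_rep")]
  meta$sample_id <- sprintf("S%04d", seq_len(n))
  meta$tissue <- unname(tissue_of[meta$cell_line])
  # cultures (cell line x bio rep) are injected in random order, with the
  # technical repeat injections of a culture consecutive; confluency is a
  # property of the culture and therefore shared by its technical replicates
  culture <- paste(meta$cell_line, meta$bio_rep)
  cultures <- unique(culture)
  culture_pos <- stats::setNames(sample.int(length(cultures)), cultures)
  ord <- order(culture_pos[culture], meta$tech_rep)
  meta$injection_index[ord] <- seq_len(n)
  conf_culture <- stats::setNames(stats::runif(length(cultures), 0.3, 1.0),
                                  cultures)
  meta$confluency <- unname(conf_culture[culture])
  # batch (experiment round) and plate (culture plate) are culture-level:
  # technical replicates share them, biological replicates usually do not,
  # and neither is contiguous in injection order
  batch_of_culture <- stats::setNames(
    sprintf("B%02d", sample.int(cfg$n_batches, length(cultures),
                                replace = TRUE)), cultures)
  plate_of_culture <- stats::setNames(
    sprintf("P%02d", sample.int(cfg$n_plates, length(cultures),
                                replace = TRUE)), cultures)
  meta$batch <- unname(batch_of_culture[culture])
  meta$plate <- unname(plate_of_culture[culture])
  dt_line <- stats::setNames(stats::rlnorm(nl, log(35), 0.3), lines)
  meta$doubling_time <- unname(dt_line[meta$cell_line])
  meta <- meta[, c("sample_id", "cell_line", "tissue", "bio_rep", "tech_rep",
                   "injection_index", "confluency", "batch", "plate",
                   "doubling_time")]

  baseline <- stats::rnorm(nf, cfg$baseline_log_mean, cfg$baseline_log_sd)
  tissue_eff <- matrix(stats::rnorm(cfg$n_tissues * nf, 0, cfg$tissue_sd),
                       cfg$n_tissues, nf, dimnames = list(tissues, feats))
  # cell-line effects: shared latent metabolic programs plus an independent
  # residual, so non-replicate distances spread instead of concentrating
  k <- cfg$n_latent_factors
  loadings <- matrix(stats::rnorm(k * nf, 0, 1 / sqrt(k)), k, nf)
  factors <- matrix(stats::rnorm(nl * k), nl, k)
  line_eff <- cfg$between_line_sd *
    (sqrt(cfg$latent_frac) * factors %*% loadings +
       sqrt(1 - cfg$latent_frac) * matrix(stats::rnorm(nl * nf), nl, nf))
  dimnames(line_eff) <- list(lines, feats)
  bio_key <- paste(meta$cell_line, meta$bio_rep)
  ubio <- unique(bio_key)
  outlier <- stats::runif(length(ubio)) < cfg$bio_outlier_frac
  bio_sd <- cfg$noise_sd_bio * ifelse(outlier, cfg$bio_outlier_mult, 1)
  bio_eff <- matrix(stats::rnorm(length(ubio) * nf), length(ubio), nf,
                    dimnames = list(ubio, feats)) * bio_sd
  outlier_cultures <- ubio[outlier]

  drift_scale <- stats::runif(nf, 0.5, 1.5)
  drift_base <- cfg$drift_amplitude * drift_shape(seq_len(n) / n)

  batch_feats <- character(0)
  batch_off <- plate_off <- NULL
  n_batch_feats <- floor(cfg$batch_frac * nf)
  if (n_batch_feats > 0) {
    batch_feats <- sort(sample(feats, n_batch_feats))
    batches <- sort(unique(meta$batch))
    plates <- sort(unique(meta$plate))
    batch_off <- matrix(stats::rnorm(length(batches) * n_batch_feats, 0,
                                     cfg$batch_effect_sd),
                        length(batches), n_batch_feats,
                        dimnames = list(batches, batch_feats))
    plate_off <- matrix(stats::rnorm(length(plates) * n_batch_feats, 0,
                                     cfg$batch_effect_sd / 2),
                        length(plates), n_batch_feats,
                        dimnames = list(plates, batch_feats))
  }

  lv <- matrix(baseline, n, nf, byrow = TRUE,
               dimnames = list(meta$sample_id, feats))
  lv <- lv + tissue_eff[meta$tissue, , drop = FALSE] +
    line_eff[meta$cell_line, , drop = FALSE] +
    bio_eff[bio_key, , drop = FALSE] +
    matrix(stats::rnorm(n * nf, 0, cfg$noise_sd_tech), n, nf)
  lv <- lv + outer(drift_base[meta$injection_index], drift_scale)
  lv <- lv + cfg$confluency_effect * (meta$confluency - 0.65)
  if (n_batch_feats > 0) {
    lv[, batch_feats] <- lv[, batch_feats] +
      batch_off[meta$batch, , drop = FALSE] +
      plate_off[meta$plate, , drop = FALSE]
  }

  truth <- list(
    config = unclass(cfg),
    tissue_of_line = as.list(tissue_of),
    doubling_time = as.list(dt_line),
    drift = list(injection_index = seq_len(n), offset = drift_base,
                 feature_scale = stats::setNames(drift_scale, feats)),
    confluency_effect = cfg$confluency_effect,
    batch_features = batch_feats,
    outlier_cultures = outlier_cultures,
    planted_gene_effects = list(),
    planted_score_couplings = list(),
    planted_drug_couplings = list(),
    synergy_pairs = list()
  )
  list(matrix = feature_matrix(exp(lv), stage = "raw"),
       meta = meta, truth = truth)
}

#' Generate random pathway definitions
#'
#' Draws named subsets of the feature universe with sizes uniform on
#' `size_range`; overlaps between pathways are allowed.
#'
#' @param n_pathways number of pathways.
#' @param size_range integer vector `c(min, max)` of member counts.
#' @param universe feature ID vector.
#' @param seed integer seed.
#' @return a [pathway_db()].
#' @export
generate_pathways <- function(n_pathways, size_range, universe, seed) {
  if (!length(universe)) stop("`universe` is empty")
  if (max(size_range) > length(universe))
    stop("maximum pathway size exceeds universe size")
  if (min(size_range) < 1) stop("pathway sizes must be positive")
  withr::with_seed(seed, {
    sizes <- size_range[1] +
      sample.int(size_range[2] - size_range[1] + 1L, n_pathways,
                 replace = TRUE) - 1L
    sets <- lapply(sizes, function(k) sort(sample(universe, k)))
    names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
    pathway_db(sets, universe)
  })
}

#' Plant mutation effects into a study
#'
#' Assigns a ternary mutation status (WT / mutant / missing) per cell line and
#' gene, constant across that line's replicates, and shifts the natural-log
#' intensities of each effect's target features in mutant lines by
#' `effect` times the feature's log-scale SD. Tissue-scoped effects only
#' mutate (and shift) lines of that tissue.
#'
#' @param matrix a raw-stage [feature_matrix()] (sample level).
#' @param meta matching sample metadata.
#' @param effects list of effect specs, each a list with elements `gene`,
#'   `features` (character), `effect` (shift in feature-SD units), and
#'   optionally `tissue` (`"all"` or a tissue ID, default `"all"`),
#'   `mutant_frac` (default 0.5), `missing_frac` (default 0).
#' @param seed integer seed.
#' @return list with the shifted `matrix`, a long `mutations` data.frame
#'   (cell_line, gene, status) and a `truth` record of the planted effects.
#' @export
plant_mutation_effects <- function(matrix, meta, effects, seed) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  meta <- align_meta(matrix, meta, c("cell_line", "tissue"))
  withr::with_seed(seed, {
    lv <- log(fm_values(matrix))
    lines <- unique(meta$cell_line)
    tissue_of <- meta$tissue[match(lines, meta$cell_line)]
    mut_rows <- list()
    truth <- list()
    for (sp in effects) {
      tissue <- if (is.null(sp$tissue)) "all" else sp$tissue
      mut_frac <- if (is.null(sp$mutant_frac)) 0.5 else sp$mutant_frac
      miss_frac <- if (is.null(sp$missing_frac)) 0 else sp$missing_frac
      if (!all(sp$features %in% colnames(lv)))
        stop("effect targets unknown features")
      scope <- if (identical(tissue, "all")) lines else {
        if (!tissue %in% tissue_of) stop("effect tissue not present: ", tissue)
        lines[tissue_of == tissue]
      }
      n_mut <- round(mut_frac * length(scope))
      warn <- NULL
      if (n_mut == 0) warn <- "zero mutant lines in scope"
      mutant <- if (n_mut > 0) sample(scope, n_mut) else character(0)
      status <- stats::setNames(rep("WT", length(lines)), lines)
      status[mutant] <- "mutant"
      n_miss <- round(miss_frac * length(lines))
      if (n_miss > 0) status[sample(lines, n_miss)] <- "missing"
      if (sp$effect != 0 && length(mutant)) {
        target_rows <- meta$cell_line %in% names(status)[status == "mutant"]
        for (f in sp$features) {
          lv[target_rows, f] <- lv[target_rows, f] +
            sp$effect * stats::sd(lv[, f])
        }
      }
      mut_rows[[sp$gene]] <- data.frame(cell_line = lines, gene = sp$gene,
                                        status = unname(status[lines]),
                                        stringsAsFactors = FALSE)
      truth[[sp$gene]] <- list(gene = sp$gene, features = sp$features,
                               effect = sp$effect, tissue = tissue,
                               mutant_lines = sort(mutant), warning = warn)
      if (!is.null(warn)) warning(sp$gene, ": ", warn)
    }
    list(matrix = feature_matrix(exp(lv), stage = fm_stage(matrix)),
         mutations = do.call(rbind, c(mut_rows, make.row.names = FALSE)),
         truth = list(planted_gene_effects = truth))
  })
}

#' Generate coupled score, drug-response and synergy tables
#'
#' Each coupled score or drug value per cell line is
#' `sign * strength * mean(z)` over the coupled pathway's members in that
#' line, plus Gaussian noise; uncoupled columns are pure noise. Drug pairs
#' coupled with opposite signs to the same pathway are emitted as synergy
#' pairs with a positive ZIP score.
#'
#' @param matrix a cell-line level [feature_matrix()] (any stage; member
#'   z-scores are computed internally).
#' @param pathways a [pathway_db()] over the matrix features.
#' @param couplings data.frame with columns `name`, `pathway`, `sign`
#'   (+1/-1), `strength`, `kind` (`"program"` or `"drug_ic50"`), and
#'   optionally `noise_sd` (default `noise_sd`).
#' @param seed integer seed.
#' @param n_noise_scores,n_noise_drugs uncoupled pure-noise columns to add.
#' @param noise_sd default noise SD for all columns.
#' @return list with `scores` (lines x score matrix), `score_kind`, `drugs`
#'   (lines x drug ln IC50 matrix), `synergy` data.frame
#'   (drug_a, drug_b, zip_score, synergy) and a `truth` record.
#' @export
generate_scores_and_drugs <- function(matrix, pathways, couplings, seed,
                                      n_noise_scores = 2, n_noise_drugs = 2,
                                      noise_sd = 0.3) {
  stopifnot(inherits(matrix, "FeatureMatrix"), inherits(pathways, "PathwayDB"))
  v <- fm_values(matrix)
  zm <- scale(v)
  zm[, apply(v, 2, stats::sd) == 0] <- 0
  withr::with_seed(seed, {
    nl <- nrow(zm)
    cols <- list()
    kinds <- character(0)
    for (i in seq_len(nrow(couplings))) {
      cp <- couplings[i, ]
      members <- intersect(pathways$pathways[[cp$pathway]], colnames(zm))
      if (is.null(pathways$pathways[[cp$pathway]]) || !length(members))
        stop("coupling to missing or empty pathway: ", cp$pathway)
      nsd <- if ("noise_sd" %in% names(cp) && !is.na(cp$noise_sd))
        cp$noise_sd else noise_sd
      base <- rowMeans(zm[, members, drop = FALSE])
      cols[[cp$name]] <- cp$sign * cp$strength * base +
        stats::rnorm(nl, 0, nsd)
      kinds[cp$name] <- cp$kind
    }
    for (j in seq_len(n_noise_scores)) {
      nm <- sprintf("noise_score_%02d", j)
      cols[[nm]] <- stats::rnorm(nl, 0, max(noise_sd, 1))
      kinds[nm] <- "program"
    }
    for (j in seq_len(n_noise_drugs)) {
      nm <- sprintf("noise_drug_%02d", j)
      cols[[nm]] <- stats::rnorm(nl, 0, max(noise_sd, 1))
      kinds[nm] <- "drug_ic50"
    }
    all_mat <- do.call(cbind, cols)
    rownames(all_mat) <- rownames(zm)
    scores <- all_mat[, kinds[colnames(all_mat)] != "drug_ic50", drop = FALSE]
    drugs <- all_mat[, kinds[colnames(all_mat)] == "drug_ic50", drop = FALSE]

    # drugs with opposite couplings to one pathway are synergistic by design
    dcp <- couplings[couplings$kind == "drug_ic50", , drop = FALSE]
    syn <- NULL
    if (nrow(dcp) > 1) {
      pairs <- utils::combn(nrow(dcp), 2)
      keep <- apply(pairs, 2, function(ij) {
        dcp$pathway[ij[1]] == dcp$pathway[ij[2]] &&
          dcp$sign[ij[1]] * dcp$sign[ij[2]] < 0
      })
      if (any(keep)) {
        pairs <- pairs[, keep, drop = FALSE]
        syn <- data.frame(drug_a = dcp$name[pairs[1, ]],
                          drug_b = dcp$name[pairs[2, ]],
                          zip_score = stats::runif(sum(keep), 0.5, 3),
                          stringsAsFactors = FALSE)
        syn$synergy <- syn$zip_score > 0
      }
    }
    if (is.null(syn))
      syn <- data.frame(drug_a = character(0), drug_b = character(0),
                        zip_score = numeric(0), synergy = logical(0))
    list(scores = scores, score_kind = kinds[colnames(scores)],
         drugs = drugs, synergy = syn,
         truth = list(planted_score_couplings =
                        couplings[couplings$kind != "drug_ic50", ],
                      planted_drug_couplings = dcp,
                      synergy_pairs = syn))
  })
}
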