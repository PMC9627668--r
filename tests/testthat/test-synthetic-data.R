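test_that("study_config validates its inputs", {
  expect_error(study_config(), "seed")
  expect_error(study_config(seed = 1, n_cell_lines = 0), "positive")
  expect_error(study_config(seed = 1, batch_frac = 1.5), "batch_frac")
  expect_warning(study_config(seed = 1, noise_sd_tech = 1, noise_sd_bio = 0.1),
                 "ordering")
})

test_that("generate_study matches the design arithmetic and is deterministic", {
  cfg <- study_config(seed = 7, n_cell_lines = 20, n_tissues = 4,
                      n_bio_reps = 3, n_tech_reps = 2, n_features = 50)
  st <- generate_study(cfg)
  expect_equal(nrow(st$matrix), 20 * 3 * 2)
  expect_equal(ncol(st$matrix), 50)
  expect_equal(sort(st$meta$injection_index), 1:120)
  expect_true(all(st$meta$confluency > 0.3 & st$meta$confluency < 1))
  expect_equal(length(unique(st$meta$tissue)), 4)
  expect_true(all(fm_values(st$matrix) > 0))
  # per-line replicate count
  expect_true(all(table(st$meta$cell_line) == 6))
  # bit-identical rerun
  st2 <- generate_study(cfg)
  expect_identical(st$matrix, st2$matrix)
  expect_identical(st$meta, st2$meta)
  # different seed differs
  st3 <- generate_study(study_config(seed = 8, n_cell_lines = 20,
                                     n_tissues = 4, n_features = 50))
  expect_false(identical(fm_values(st$matrix), fm_values(st3$matrix)))
})

test_that("zero-noise degenerate study has identical replicates", {
  cfg <- study_config(seed = 3, n_cell_lines = 4, n_tissues = 2,
                      n_features = 10, noise_sd_tech = 0, noise_sd_bio = 0,
                      drift_amplitude = 0, confluency_effect = 0,
                      batch_frac = 0, bio_outlier_frac = 0)
  st <- generate_study(cfg)
  v <- fm_values(st$matrix)
  for (cl in unique(st$meta$cell_line)) {
    rows <- v[st$meta$sample_id[st$meta$cell_line == cl], , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
  }
})

test_that("generate_pathways respects sizes, universe and seed", {
  uni <- sprintf("M%03d", 1:500)
  db <- generate_pathways(50, c(5, 30), uni, seed = 4)
  expect_length(db$pathways, 50)
  expect_true(all(unlist(db$pathways) %in% uni))
  expect_true(all(lengths(db$pathways) >= 5 & lengths(db$pathways) <= 30))
  expect_identical(db, generate_pathways(50, c(5, 30), uni, seed = 4))
  # single pathway spanning the whole universe
  db1 <- generate_pathways(1, c(10, 10), sprintf("x%d", 1:10), seed = 1)
  expect_setequal(db1$pathways[[1]], db1$universe)
  expect_error(generate_pathways(1, c(1, 5), character(0), seed = 1), "empty")
  expect_error(generate_pathways(1, c(11, 11), sprintf("x%d", 1:10), seed = 1),
               "exceeds")
})

test_that("plant_mutation_effects obeys the planting rule exactly", {
  cfg <- study_config(seed = 5, n_cell_lines = 10, n_tissues = 2,
                      n_features = 12, noise_sd_tech = 0, noise_sd_bio = 0,
                      drift_amplitude = 0, confluency_effect = 0,
                      batch_frac = 0, bio_outlier_frac = 0)
  st <- generate_study(cfg)
  pl <- plant_mutation_effects(st$matrix, st$meta,
                               list(list(gene = "G1", features = "M0003",
                                         effect = 2, mutant_frac = 0.5)),
                               seed = 6)
  lv <- log(fm_values(st$matrix))
  lv2 <- log(fm_values(pl$matrix))
  mut_lines <- pl$truth$planted_gene_effects$G1$mutant_lines
  expect_length(mut_lines, 5)
  mut_rows <- st$meta$cell_line %in% mut_lines
  shift <- lv2[, "M0003"] - lv[, "M0003"]
  sd_f <- sd(lv[, "M0003"])
  expect_equal(unname(shift[mut_rows]), rep(2 * sd_f, sum(mut_rows)))
  expect_equal(unname(shift[!mut_rows]), rep(0, sum(!mut_rows)))
  # untouched features unchanged
  expect_equal(lv2[, -3], lv[, -3])
  # status constant across replicates, ternary coding
  expect_setequal(unique(pl$mutations$status), c("WT", "mutant"))
  # zero effect leaves the matrix unchanged
  pl0 <- plant_mutation_effects(st$matrix, st$meta,
                                list(list(gene = "G2", features = "M0001",
                                          effect = 0)), seed = 6)
  expect_equal(fm_values(pl0$matrix), fm_values(st$matrix))
})

test_that("tissue-scoped effects leave other tissues untouched", {
  cfg <- study_config(seed = 5, n_cell_lines = 10, n_tissues = 2,
                      n_features = 8, noise_sd_tech = 0, noise_sd_bio = 0,
                      drift_amplitude = 0, confluency_effect = 0,
                      batch_frac = 0, bio_outlier_frac = 0)
  st <- generate_study(cfg)
  pl <- plant_mutation_effects(st$matrix, st$meta,
                               list(list(gene = "G1", features = "M0002",
                                         effect = 1.5, tissue = "T01",
                                         mutant_frac = 0.6)),
                               seed = 2)
  other <- st$meta$tissue != "T01"
  expect_equal(fm_values(pl$matrix)[other, ], fm_values(st$matrix)[other, ])
  mut_lines <- pl$truth$planted_gene_effects$G1$mutant_lines
  expect_true(all(st$meta$tissue[st$meta$cell_line %in% mut_lines] == "T01"))
})

test_that("generate_scores_and_drugs produces exact couplings at zero noise", {
  st <- small_study(seed = 9)
  avg <- average_biological_replicates(zscore_features(st$matrix), st$meta)
  db <- generate_pathways(5, c(4, 8), colnames(avg), seed = 2)
  cpl <- data.frame(name = c("sA", "dPos", "dNeg"),
                    pathway = c("PW001", "PW002", "PW002"),
                    sign = c(1, 1, -1), strength = 1,
                    kind = c("program", "drug_ic50", "drug_ic50"),
                    noise_sd = 0)
  out <- generate_scores_and_drugs(avg, db, cpl, seed = 3,
                                   n_noise_scores = 1, n_noise_drugs = 1)
  zm <- scale(fm_values(avg))
  base <- rowMeans(zm[, db$pathways$PW002])
  expect_equal(unname(out$drugs[, "dPos"]), unname(base))
  expect_equal(unname(out$drugs[, "dNeg"]), unname(-base))
  expect_equal(cor(out$drugs[, "dPos"], out$drugs[, "dNeg"]), -1)
  # opposite-sign couplings to one pathway are emitted as a synergy pair
  expect_equal(nrow(out$synergy), 1)
  expect_true(out$synergy$zip_score > 0)
  expect_error(
    generate_scores_and_drugs(avg, db,
                              data.frame(name = "x", pathway = "nope",
                                         sign = 1, strength = 1,
                                         kind = "program"), seed = 1),
    "missing or empty")
})
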