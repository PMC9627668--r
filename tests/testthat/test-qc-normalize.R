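test_that("replicate_roc_auc handles perfect separation and all-ties", {
  ts <- tiny_study()
  # identical replicates within a bio rep, distinct across cell lines
  v <- fm_values(ts$matrix)
  lv <- matrix(rep(c(10, 11, 14, 15), each = 2), 8, 3)
  dimnames(lv) <- dimnames(v)
  m <- feature_matrix(exp(lv), stage = "raw")
  expect_equal(replicate_roc_auc(m, ts$meta, "technical"), 1)
  # constant matrix: every distance 0, all ties
  mc <- feature_matrix(matrix(exp(10), 8, 3, dimnames = dimnames(v)), "raw")
  expect_equal(replicate_roc_auc(mc, ts$meta, "technical"), 0.5)
  expect_equal(replicate_roc_auc(mc, ts$meta, "biological"), 0.5)
})

test_that("replicate_roc_auc agrees with an explicit pair-comparison oracle", {
  st <- small_study(seed = 21)
  d <- as.matrix(dist(log10(fm_values(st$matrix))))
  meta <- st$meta
  for (level in c("technical", "biological")) {
    pos <- neg <- c()
    for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
      same_line <- meta$cell_line[i] == meta$cell_line[j]
      same_bio <- same_line && meta$bio_rep[i] == meta$bio_rep[j]
      is_pos <- if (level == "technical") same_bio else same_line && !same_bio
      if (is_pos) pos <- c(pos, d[i, j]) else neg <- c(neg, d[i, j])
    }
    expect_equal(replicate_roc_auc(st$matrix, meta, level),
                 oracle_auc(pos, neg))
  }
})

test_that("replicate_roc_auc errors without both pair classes", {
  ts <- tiny_study()
  meta1 <- ts$meta
  meta1$cell_line <- "CL1"
  meta1$bio_rep <- 1  # all pairs positive at the technical level
  expect_error(replicate_roc_auc(ts$matrix, meta1, "technical"), "undefined")
})

test_that("drift correction flattens planted trends and is identity without", {
  # flat input (no variation at all): correction is the identity
  st <- small_study(seed = 2, drift_amplitude = 0, confluency_effect = 0,
                    batch_frac = 0, noise_sd_tech = 0, noise_sd_bio = 0,
                    between_line_sd = 0, tissue_sd = 0, bio_outlier_frac = 0)
  out <- correct_injection_drift(st$matrix, st$meta)
  expect_lt(max(abs(log(fm_values(out)) - log(fm_values(st$matrix)))), 1e-8)
  expect_equal(fm_stage(out), "drift_corrected")

  std <- small_study(seed = 3, n_cell_lines = 10, n_features = 30,
                     drift_amplitude = 1.5, confluency_effect = 0,
                     batch_frac = 0)
  inj <- std$meta$injection_index
  pre <- apply(log(fm_values(std$matrix)), 2, cor, inj)
  post <- apply(log(fm_values(correct_injection_drift(std$matrix, std$meta))),
                2, cor, inj)
  expect_gt(median(abs(pre)), 0.4)
  expect_lt(median(abs(post)), 0.1)
  # constant feature passes through unchanged
  ts <- tiny_study()
  v <- fm_values(ts$matrix); v[, 2] <- exp(10)
  ts10 <- small_study(seed = 4, n_features = 5)
  vv <- fm_values(ts10$matrix); vv[, 2] <- exp(10)
  m <- feature_matrix(vv, stage = "raw")
  out2 <- correct_injection_drift(m, ts10$meta)
  expect_equal(unname(fm_values(out2)[, 2]), rep(exp(10), nrow(m)))
  expect_error(correct_injection_drift(ts$matrix, ts$meta), "10")
})

test_that("low-intensity injection removal applies the log2-sum rule", {
  st <- small_study(seed = 5)
  keep_all <- drop_low_intensity_injections(st$matrix, 0)
  expect_length(keep_all$removed, 0)
  v <- fm_values(st$matrix)
  v["S0003", ] <- v["S0003", ] / sum(v["S0003", ]) * 2^24
  m <- feature_matrix(v, stage = "raw")
  out <- drop_low_intensity_injections(m, 25)
  expect_identical(out$removed, "S0003")
  expect_false("S0003" %in% rownames(out$matrix))
  expect_error(drop_low_intensity_injections(m, 99), "below")
})

test_that("confluency correction removes the planted total-intensity trend", {
  st <- small_study(seed = 6, n_cell_lines = 12, confluency_effect = 1.5,
                    drift_amplitude = 0, batch_frac = 0)
  tot_pre <- log(rowSums(fm_values(st$matrix)))
  rho_pre <- cor(tot_pre, st$meta$confluency, method = "spearman")
  out <- correct_confluency(st$matrix, st$meta)
  tot_post <- log(rowSums(fm_values(out)))
  rho_post <- cor(tot_post, st$meta$confluency, method = "spearman")
  expect_gt(abs(rho_pre), 0.5)
  expect_lt(abs(rho_post), 0.1)
  # confluency-independent flat input is the identity
  st0 <- small_study(seed = 7, confluency_effect = 0, drift_amplitude = 0,
                     batch_frac = 0, noise_sd_tech = 0, noise_sd_bio = 0,
                     between_line_sd = 0, tissue_sd = 0, bio_outlier_frac = 0)
  out0 <- correct_confluency(st0$matrix, st0$meta)
  expect_lt(max(abs(log(fm_values(out0)) - log(fm_values(st0$matrix)))), 1e-8)
  # constant confluency: identity with warning
  meta_const <- st0$meta; meta_const$confluency <- 0.5
  expect_warning(outc <- correct_confluency(st0$matrix, meta_const),
                 "constant")
  expect_equal(fm_values(outc), fm_values(st0$matrix))
  # too few samples
  ts <- tiny_study()
  expect_error(correct_confluency(ts$matrix, ts$meta), "10")
})

test_that("batch_plate_filter contract: preconditions, sweep, max_remove = 0", {
  st <- small_study(seed = 8, n_cell_lines = 10, n_features = 30,
                    batch_frac = 0.2, batch_effect_sd = 0.8)
  bp <- batch_plate_filter(st$matrix, st$meta, max_remove = 10)
  expect_equal(bp$report$sweep_curve$n_removed[1], 0)
  expect_equal(bp$report$sweep_curve$auc_biological[1],
               replicate_roc_auc(st$matrix, st$meta, "biological"))
  expect_true(all(bp$report$removed_features %in% colnames(st$matrix)))
  # max_remove = 0 is the identity on features
  bp0 <- batch_plate_filter(st$matrix, st$meta, max_remove = 0)
  expect_equal(colnames(bp0$matrix), colnames(st$matrix))
  # single batch and plate: precondition error
  meta1 <- st$meta; meta1$batch <- "B1"; meta1$plate <- "P1"
  expect_error(batch_plate_filter(st$matrix, meta1, 5), "2 batches")
  expect_error(batch_plate_filter(st$matrix, st$meta, 30), "max_remove")
})

test_that("zscore_features standardises, drops constants, is idempotent", {
  st <- small_study(seed = 9)
  z <- zscore_features(st$matrix)
  expect_lt(max(abs(colMeans(fm_values(z)))), 1e-9)
  expect_lt(max(abs(apply(fm_values(z), 2, sd) - 1)), 1e-9)
  expect_equal(fm_stage(z), "zscored")
  # {1,2,3} -> {-1,0,1} with sample SD
  m <- feature_matrix(matrix(c(1, 2, 3), 3, 1,
                             dimnames = list(c("a", "b", "c"), "f")),
                      stage = "zscored")
  expect_equal(unname(fm_values(zscore_features(m))[, 1]), c(-1, 0, 1))
  # idempotence
  z2 <- zscore_features(z)
  expect_lt(max(abs(fm_values(z2) - fm_values(z))), 1e-12)
  # constant feature dropped with warning
  v <- fm_values(st$matrix); v[, 3] <- exp(5)
  expect_warning(zc <- zscore_features(feature_matrix(v, "raw")),
                 "zero-variance")
  expect_false(colnames(st$matrix)[3] %in% colnames(zc))
  expect_error(zscore_features(feature_matrix(v[1, , drop = FALSE], "raw")),
               "2 samples")
})

test_that("average_biological_replicates averages tech reps then bio reps", {
  ts <- tiny_study()
  # CL1 bio means 2, 4 -> 3 ; unbalanced tech reps still weight bios equally
  lv <- matrix(0, 8, 3, dimnames = dimnames(fm_values(ts$matrix)))
  lv[1:2, ] <- 2          # CL1 bio 1 (2 tech reps)
  lv[3:4, ] <- c(3, 5)    # CL1 bio 2, tech means 4
  lv[5:8, ] <- 7          # CL2
  m <- feature_matrix(exp(lv), stage = "raw")
  meta <- ts$meta
  avg <- average_biological_replicates(
    feature_matrix(lv, stage = "zscored"), meta)
  expect_equal(unname(fm_values(avg)["CL1", 1]), 3)
  expect_equal(unname(fm_values(avg)["CL2", 1]), 7)
  expect_equal(fm_stage(avg), "cellline_avg")
  # dropping one tech rep of CL1 bio 2 leaves bio weighting equal
  keep <- rownames(m)[-4]
  avg2 <- average_biological_replicates(
    feature_matrix(lv[keep, ], stage = "zscored"), meta)
  expect_equal(unname(fm_values(avg2)["CL1", 1]), mean(c(2, 3)))
})

test_that("full chain raises biological AUC on an artifact-laden study", {
  st <- small_study(seed = 10, n_cell_lines = 12, n_features = 60,
                    batch_frac = 0.15)
  raw_bio <- replicate_roc_auc(st$matrix, st$meta, "biological")
  m1 <- correct_injection_drift(st$matrix, st$meta)
  m2 <- correct_confluency(drop_low_intensity_injections(m1)$matrix, st$meta)
  bf <- batch_plate_filter(m2, st$meta, max_remove = 15)
  expect_gt(bf$report$auc_biological, raw_bio)
})
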