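test_that("compute_rank_profile: rank arithmetic and tie handling", {
  v <- matrix(c(3, 2, 1,
                1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("L1", "L2"), c("f1", "f2", "f3")))
  rp <- compute_rank_profile(feature_matrix(v, "cellline_avg"))
  # bulk means all equal -> bulk ranks all tied at 2
  expect_equal(unname(rp$bulk_rank), c(2, 2, 2))
  # L2 reversed vs L1
  expect_equal(unname(rp$delta["L1", ]), c(1, 0, -1))
  expect_equal(unname(rp$delta["L2", ]), c(-1, 0, 1))
  # line identical to bulk ordering -> delta 0
  v2 <- matrix(c(5, 3, 1, 10, 6, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("L1", "L2"), c("f1", "f2", "f3")))
  rp2 <- compute_rank_profile(feature_matrix(v2, "cellline_avg"))
  expect_equal(unname(rp2$delta["L1", ]), c(0, 0, 0))
  # ties within a line share the average rank
  v3 <- matrix(c(4, 4, 1, 9, 5, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("L1", "L2"), c("f1", "f2", "f3")))
  rp3 <- compute_rank_profile(feature_matrix(v3, "cellline_avg"))
  expect_equal(unname(rp3$sample_rank["L1", 1:2]), c(1.5, 1.5))
  # delta sums to zero per line without ties
  st <- small_study(seed = 2)
  avg <- average_biological_replicates(st$matrix, st$meta, log10 = TRUE)
  rp4 <- compute_rank_profile(avg)
  expect_lt(max(abs(rowSums(rp4$delta))), 1e-8)
})

test_that("min_hypergeometric matches the enumeration oracle (N <= 8, K <= 3)", {
  for (N in 3:8) for (K in 1:min(3, N - 1)) {
    subsets <- utils::combn(N, K)
    for (ci in seq_len(ncol(subsets))) {
      flags <- logical(N); flags[subsets[, ci]] <- TRUE
      got <- min_hypergeometric(flags, "permutation")
      exp <- oracle_mhg(flags)
      expect_equal(got$s, exp$s, tolerance = 1e-12)
      expect_equal(got$p, exp$p, tolerance = 1e-12)
      expect_true(got$exhaustive)
    }
  }
})

test_that("min_hypergeometric closed cases and degenerate inputs", {
  r <- min_hypergeometric(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), "permutation")
  expect_equal(r$s, 1 / choose(8, 3))
  expect_equal(r$p, 1 / choose(8, 3))
  r2 <- min_hypergeometric(c(rep(FALSE, 5), TRUE, TRUE, TRUE), "permutation")
  expect_equal(r2$p, 1)
  expect_error(min_hypergeometric(rep(FALSE, 4)), "no members")
  expect_equal(min_hypergeometric(rep(TRUE, 4))$p, 1)
  # bonferroni bound
  rb <- min_hypergeometric(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), "bonferroni")
  expect_equal(rb$p, min(1, rb$s * 3))
})

test_that("pathway_activity: null line, planted shift, threshold scaling", {
  st <- small_study(seed = 3, n_cell_lines = 10, n_features = 50)
  avg <- average_biological_replicates(st$matrix, st$meta, log10 = TRUE)
  db <- generate_pathways(6, c(5, 8), colnames(avg), seed = 1)
  act <- pathway_activity(avg, db)
  # invariants: direction none whenever p >= alpha; |rsc| bounded
  expect_true(all(act$direction[act$pvalue >= 0.05] == "none"))
  nf <- ncol(avg)
  for (pw in colnames(act$rank_sum_change)) {
    k <- length(intersect(db$pathways[[pw]], colnames(avg)))
    expect_true(all(abs(act$rank_sum_change[, pw]) <= k * (nf - 1)))
  }
  expect_equal(act$params$threshold_scaled, 350 * nf / 1099)
  # plant: lift pathway members well up one line's ordering (modest shift,
  # so the bulk ordering stays put)
  v <- fm_values(avg)
  memb <- db$pathways[[1]]
  v["CL001", memb] <- v["CL001", memb] + 3
  act2 <- pathway_activity(feature_matrix(v, "cellline_avg"), db)
  pw1 <- names(db$pathways)[1]
  expect_gt(act2$rank_sum_change["CL001", pw1], 0)
  expect_lt(act2$pvalue["CL001", pw1], 0.05)
  expect_equal(act2$direction["CL001", pw1], "increased")
})

test_that("rank_sum_change is antisymmetric under order reversal", {
  st <- small_study(seed = 4, n_cell_lines = 6, n_features = 30)
  avg <- average_biological_replicates(st$matrix, st$meta, log10 = TRUE)
  db <- generate_pathways(4, c(4, 8), colnames(avg), seed = 2)
  act <- pathway_activity(avg, db)
  # negating the data reverses every ordering, bulk included (no ties)
  act2 <- pathway_activity(feature_matrix(-fm_values(avg), "cellline_avg"), db)
  expect_equal(act2$rank_sum_change, -act$rank_sum_change)
})

test_that("doubling_time_regression recovers a perfect linear relation", {
  st <- small_study(seed = 5, n_cell_lines = 10, n_features = 40)
  avg <- average_biological_replicates(st$matrix, st$meta, log10 = TRUE)
  db <- generate_pathways(4, c(4, 8), colnames(avg), seed = 3)
  act <- pathway_activity(avg, db)
  meta <- st$meta
  pw <- colnames(act$rank_sum_change)[1]
  dt_line <- 30 + 2 * act$rank_sum_change[, pw]
  meta$doubling_time <- dt_line[match(meta$cell_line, rownames(avg))]
  res <- doubling_time_regression(act, meta)
  row <- res[res$pathway == pw, ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_equal(row$slope, 2, tolerance = 1e-12)
  expect_gt(row$p_raw, 0)  # smallest positive, never exactly zero
  # too few lines errors
  meta4 <- meta[meta$cell_line %in% rownames(avg)[1:4], ]
  act4 <- act; act4$rank_sum_change <- act$rank_sum_change[1:4, ]
  expect_error(doubling_time_regression(act4, meta4), "5 cell lines")
})

test_that("ora closed forms and relabeling invariance", {
  uni <- letters[1:10]
  db <- pathway_db(list(P1 = c("a", "b", "c"), P2 = uni), uni)
  res <- ora(c("a", "b", "c"), db)
  expect_equal(res$p_raw[res$pathway == "P1"], 1 / choose(10, 3))
  expect_equal(res$p_raw[res$pathway == "P2"], 1)
  # disjoint selection from a half-universe pathway: p >= 0.5
  db2 <- pathway_db(list(H = letters[1:5]), uni)
  res2 <- ora(letters[6:8], db2)
  expect_gte(res2$p_raw[1], 0.5)
  # relabeling features leaves p unchanged
  relab <- setNames(sprintf("z%02d", 1:10), uni)
  db3 <- pathway_db(list(P1 = unname(relab[c("a", "b", "c")]),
                         P2 = unname(relab)), unname(relab))
  res3 <- ora(unname(relab[c("a", "b", "c")]), db3)
  expect_equal(res3$p_raw, res$p_raw)
  expect_error(ora(character(0), db), "empty")
  expect_error(ora(c("nope"), db), "outside")
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # agrees with the reference implementation on random input
  set.seed(1)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
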