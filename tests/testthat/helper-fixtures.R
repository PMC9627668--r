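# small fixtures shared across the suite; everything is built in code

# tiny hand-specified matrix + metadata: 2 cell lines x 2 bio reps x 2 tech
# reps, 3 features, no artifacts
tiny_study <- function(values = NULL) {
  meta <- expand.grid(tech_rep = 1:2, bio_rep = 1:2,
                      cell_line = c("CL1", "CL2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("S%02d", seq_len(nrow(meta)))
  meta$tissue <- ifelse(meta$cell_line == "CL1", "T1", "T2")
  meta$injection_index <- seq_len(nrow(meta))
  meta$confluency <- 0.7
  meta$batch <- "B1"
  meta$plate <- "P1"
  meta$doubling_time <- 30
  if (is.null(values)) {
    values <- matrix(exp(10 + seq_len(nrow(meta) * 3) / 10),
                     nrow(meta), 3)
  }
  dimnames(values) <- list(meta$sample_id, c("f1", "f2", "f3"))
  list(matrix = feature_matrix(values, stage = "raw"), meta = meta)
}

# compact synthetic study for module tests (fast defaults)
small_study <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_cell_lines = 8, n_tissues = 2, n_features = 40),
    list(...))
  generate_study(do.call(study_config, args))
}

# independent mHG oracle: tail probabilities by summing dhyper over ALL
# prefix lengths (not just member positions), p by full enumeration
oracle_mhg <- function(flags) {
  N <- length(flags); K <- sum(flags)
  s_of <- function(fl) {
    k <- cumsum(fl)
    min(vapply(seq_len(N), function(n) {
      sum(stats::dhyper(k[n]:min(K, n), K, N - K, n))
    }, 0))
  }
  s_obs <- s_of(flags)
  all_s <- utils::combn(N, K, function(pos) {
    fl <- logical(N); fl[pos] <- TRUE
    s_of(fl)
  })
  list(s = s_obs, p = mean(all_s <= s_obs * (1 + 1e-9)))
}

# independent AUC oracle: explicit pair comparisons
oracle_auc <- function(d_pos, d_neg) {
  cmp <- outer(d_pos, d_neg, function(p, n) (p < n) + 0.5 * (p == n))
  mean(cmp)
}

# brute-force two-sided Fisher p over all tables with the observed margins
oracle_fisher <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  support <- max(0, n - (N - K)):min(K, n)
  tab_p <- vapply(support, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, 0)
  p_obs <- tab_p[match(a, support)]
  sum(tab_p[tab_p <= p_obs * (1 + 1e-7)])
}
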