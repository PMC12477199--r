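# Shared fixtures and independent oracles, built in code at test time.

# Small feature table with hand-set values.
tiny_ft <- function(values = matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
                                    dimnames = list(c("c1", "c2"),
                                                    c("s1", "s2", "s3"))),
                    kind = "concentration") {
  feature_table(values, kind)
}

# Design with two stages of n replicates each, no QC.
two_stage_design <- function(n = 3, stages = c("G1", "G4")) {
  stage_design(
    sample_id = c(paste0("a", seq_len(n)), paste0("b", seq_len(n))),
    time_point = rep(c("S0", "S5"), each = n),
    stage = rep(stages, each = n),
    replicate_index = rep(seq_len(n), 2))
}

# Feature table matching two_stage_design from two per-compound group means.
two_stage_ct <- function(mean_a, mean_b, n = 3, jitter = 0) {
  m <- cbind(matrix(rep(mean_a, n), ncol = n),
             matrix(rep(mean_b, n), ncol = n))
  if (jitter > 0) m <- m * exp(matrix(stats::rnorm(length(m), 0, jitter),
                                      nrow(m)))
  dimnames(m) <- list(paste0("c", seq_along(mean_a)),
                      c(paste0("a", seq_len(n)), paste0("b", seq_len(n))))
  feature_table(m, "concentration")
}

# Quick small synthetic dataset for structural tests.
quick_dataset <- function(seed = 1, ...) {
  generate_dataset(synth_config(n_compounds = 60, n_key_up = 4,
                                n_key_down = 2, seed = seed, ...))
}

# Independent exhaustive oracle: P(X >= k) for hypergeometric(N, K, n)
# by direct combinatorial sum.
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Independent brute-force k-means oracle: minimal WCSS over all
# assignments of n points into at most k clusters.
kmeans_wcss_oracle <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  grid <- rep(list(seq_len(k)), n)
  assign_all <- as.matrix(expand.grid(grid))
  for (r in seq_len(nrow(assign_all))) {
    a <- assign_all[r, ]
    wcss <- 0
    for (cl in unique(a)) {
      pts <- X[a == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      wcss <- wcss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wcss < best) best <- wcss
  }
  best
}

# One full planted-truth recovery run on the generator defaults:
# differential screen (G1 vs G4), planted-pathway p-value, key-compound
# screen, all compared against ground truth.
recovery_run <- function(seed) {
  ds <- generate_dataset(synth_config(seed = seed))
  ct <- fill_missing(semi_quantify(ds$ft, ds$isp))
  truth <- ds$truth$trend

  res <- compare_stages(ct, ds$design, "G1", "G4", compute_q2 = FALSE,
                        seed = seed)
  called_up <- res$compound_id[res$call == "up"]
  called_down <- res$compound_id[res$call == "down"]
  true_up <- names(truth)[truth == "up"]
  true_down <- names(truth)[truth == "down"]
  tp <- length(intersect(called_up, true_up)) +
    length(intersect(called_down, true_down))
  sens_diff <- tp / (length(true_up) + length(true_down))
  prec_diff <- tp / max(1, length(called_up) + length(called_down))

  diff_set <- c(called_up, called_down)
  enr <- msea(diff_set, ds$ft$compound_ids, ds$ann)
  pathway_p <- enr$p_value[enr$pathway_id == ds$truth$enriched_pathway]

  prof <- stage_profiles(ct, ds$design)[diff_set, , drop = FALSE]
  sc <- uv_scale_profiles(prof)
  cl <- kmeans_cluster(sc$scaled, k = 8, seed = seed)
  roav <- compute_roav(ct, ds$ann, ds$design)
  keys <- screen_key_compounds(roav, cl)
  true_keys <- c(ds$truth$key_up, ds$truth$key_down)
  kp <- length(intersect(keys$compound_id, true_keys))
  list(sens_diff = sens_diff, prec_diff = prec_diff,
       pathway_p = pathway_p,
       sens_key = kp / length(true_keys),
       prec_key = kp / max(1, nrow(keys)))
}
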