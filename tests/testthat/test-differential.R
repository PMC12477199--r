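test_that("log2 fold change follows stage-mean ratios and is antisymmetric", {
  ct <- two_stage_ct(mean_a = c(2, 1, 8), mean_b = c(2, 4, 2))
  design <- two_stage_design()
  lfc <- log2_fold_change(ct, design, "G1", "G4")
  expect_equal(unname(lfc), c(0, 2, -2))
  expect_equal(log2_fold_change(ct, design, "G4", "G1"), -lfc)
  expect_error(log2_fold_change(ct, design, "G1", "G9"), "empty stage")
})

test_that("Welch test matches a hand oracle and its Student identity", {
  design <- two_stage_design(n = 4)
  a <- c(1, 1, 1, 1.000001); b <- c(100, 100, 100, 100.0001)
  m <- rbind(c1 = c(a, b))
  colnames(m) <- design$sample_id
  p <- pairwise_test(feature_table(m, "concentration"), design, "G1", "G4")
  expect_lt(p[["c1"]], 1e-6)

  # hand-computed Welch statistic on the log scale
  set.seed(2)
  x1 <- exp(stats::rnorm(4)); x2 <- exp(stats::rnorm(4, 1))
  m2 <- rbind(c1 = c(x1, x2)); colnames(m2) <- design$sample_id
  p2 <- pairwise_test(feature_table(m2, "concentration"), design,
                      "G1", "G4")
  la <- log(x1); lb <- log(x2)
  se2 <- stats::var(la) / 4 + stats::var(lb) / 4
  tstat <- (mean(la) - mean(lb)) / sqrt(se2)
  df <- se2^2 / ((stats::var(la) / 4)^2 / 3 + (stats::var(lb) / 4)^2 / 3)
  expect_equal(unname(p2), 2 * stats::pt(-abs(tstat), df),
               tolerance = 1e-12)

  # equal variances and sizes: Welch p equals Student p
  p_w <- pairwise_test(feature_table(m2, "concentration"), design,
                       "G1", "G4", method = "welch")
  p_s <- pairwise_test(feature_table(m2, "concentration"), design,
                       "G1", "G4", method = "student")
  sd_equal <- abs(stats::sd(la) - stats::sd(lb)) < 1e-12
  if (!sd_equal) {
    # force exactly equal group variances by mirroring the first group
    m3 <- rbind(c1 = c(x1, x1 * 5)); colnames(m3) <- design$sample_id
    p_w <- pairwise_test(feature_table(m3, "concentration"), design,
                         "G1", "G4", method = "welch")
    p_s <- pairwise_test(feature_table(m3, "concentration"), design,
                         "G1", "G4", method = "student")
  }
  expect_equal(p_w, p_s, tolerance = 1e-12)
})

test_that("identical groups give p = 1 by convention", {
  design <- two_stage_design()
  m <- rbind(c1 = rep(2, 6), c2 = c(1, 2, 3, 1, 2, 3))
  colnames(m) <- design$sample_id
  p <- pairwise_test(feature_table(m, "concentration"), design, "G1", "G4")
  expect_equal(p[["c1"]], 1)    # zero variance, equal means
  expect_equal(p[["c2"]], 1)    # identical replicate sets
})

test_that("the screen applies the VIP/FC/p thresholds as printed", {
  vip <- c(a = 1.5, b = 0.9, c = 2, d = 1, e = 1.2)
  lfc <- c(a = 2, b = 3, c = -1.5, d = 1, e = 0.5)
  p <- c(a = 0.001, b = 1e-5, c = 0.005, d = 0.0099, e = 1e-4)
  res <- screen_differential(vip, lfc, p)
  calls <- stats::setNames(res$call, res$compound_id)
  expect_identical(calls[["a"]], "up")
  expect_identical(calls[["b"]], "not_significant")  # VIP below 1
  expect_identical(calls[["c"]], "down")
  expect_identical(calls[["d"]], "up")               # boundaries inclusive
  expect_identical(calls[["e"]], "not_significant")  # |FC| below 1
  # p cutoff is strict
  res2 <- screen_differential(c(x = 2), c(x = 2), c(x = 0.01))
  expect_identical(res2$call, "not_significant")
  # up/down partition the significant set
  expect_true(all(res$call %in% c("up", "down", "not_significant")))
})

test_that("venn regions enumerate intersections correctly", {
  v <- venn_counts(list(A = c("a", "b"), B = c("b", "c"), C = "b"))
  expect_equal(unname(v[["A&B&C"]]), 1)
  expect_equal(unname(v[["union"]]), 3)
  expect_equal(unname(v[["A"]]), 1)       # "a" only in A
  expect_equal(unname(v[["B"]]), 1)       # "c" only in B
  v2 <- venn_counts(list(A = "x", B = "y", C = "z"))
  expect_true(all(v2[c("A&B", "A&C", "B&C", "A&B&C")] == 0))
  v3 <- venn_counts(list(A = c("p", "q"), B = c("p", "q"), C = c("p", "q")))
  expect_equal(unname(v3[["A&B&C"]]), 2)
  expect_equal(sum(v3[setdiff(names(v3), c("A&B&C", "union"))]), 0)
})

test_that("top-k ranking pools, deduplicates and breaks ties stably", {
  mk <- function(ids, lfc, p) {
    r <- screen_differential(
      stats::setNames(rep(2, length(ids)), ids),
      stats::setNames(lfc, ids), stats::setNames(p, ids))
    r
  }
  r1 <- mk(c("m1", "m2", "m3"), c(5, 4, 3), c(1e-4, 1e-4, 1e-4))
  r2 <- mk(c("m2", "m4", "m5"), c(2, 6, 2), c(1e-4, 1e-4, 1e-5))
  out <- top_k_by_fc(list(A = r1, B = r2), k = 2)
  expect_identical(out$per_comparison$A$compound_id, c("m1", "m2"))
  # tie on |lfc| = 2 broken by smaller p: m5 before m2
  expect_identical(out$per_comparison$B$compound_id, c("m4", "m5"))
  expect_setequal(out$pooled, c("m1", "m2", "m4", "m5"))
  expect_identical(out$common, character(0))
  # k larger than the set returns everything without padding
  out2 <- top_k_by_fc(list(A = r1), k = 20)
  expect_equal(nrow(out2$per_comparison$A), 3)
  # equal |lfc| and p: lexicographic id decides
  r3 <- mk(c("z", "y"), c(2, 2), c(1e-3, 1e-3))
  out3 <- top_k_by_fc(list(A = r3), k = 1)
  expect_identical(out3$per_comparison$A$compound_id, "y")
  # a compound in every top list is flagged common
  out4 <- top_k_by_fc(list(A = r1, B = mk("m1", 3, 1e-3)), k = 3)
  expect_identical(out4$common, "m1")
})
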