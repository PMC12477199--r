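isp_for <- function(samples, area = 1e6, V_s = 10, C_s = 10, M = 0.5) {
  internal_standard_params(V_s, C_s, M,
                           stats::setNames(rep(area, length(samples)),
                                           samples))
}

test_that("semi-quantification reproduces the printed formula", {
  # V_s = 10 uL, C_s = 10 ug/mL, M = 0.5 g: I_i = I_s maps to 0.2 ug/g
  m <- matrix(c(1e6, 0, 2e6, 1e6, 5e5, 1e6), nrow = 3,
              dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  ft <- feature_table(m, "peak_area")
  ct <- semi_quantify(ft, isp_for(c("s1", "s2")))
  expect_identical(ct$value_kind, "concentration")
  expect_equal(ct$values["c1", "s1"], 0.2)
  expect_equal(ct$values["c1", "s2"], 0.2)
  expect_equal(ct$values["c2", "s1"], 0)          # zero area -> zero
  # linearity: doubling the peak area doubles the concentration
  expect_equal(ct$values["c3", "s1"], 2 * ct$values["c1", "s1"])
  expect_equal(ct$values["c2", "s2"], 0.1)        # half the standard area
})

test_that("semi-quantification uses each sample's own standard area", {
  m <- matrix(c(1e6, 1e6), 1, dimnames = list("c1", c("s1", "s2")))
  isp <- internal_standard_params(10, 10, 0.5,
                                  c(s1 = 1e6, s2 = 2e6))
  ct <- semi_quantify(feature_table(m, "peak_area"), isp)
  expect_equal(unname(ct$values["c1", ]), c(0.2, 0.1))
  # non-positive standard area is a per-sample hard error
  expect_error(semi_quantify(feature_table(m, "peak_area"),
                             internal_standard_params(10, 10, 0.5,
                                                      c(s1 = 1e6, s2 = 0))),
               "s2")
})

test_that("quantification commutes with compound subsetting", {
  ds <- quick_dataset(seed = 2)
  full <- semi_quantify(ds$ft, ds$isp)
  sub_ids <- ds$ft$compound_ids[c(3, 10, 25)]
  sub <- feature_table(ds$ft$values[sub_ids, , drop = FALSE], "peak_area")
  expect_equal(semi_quantify(sub, ds$isp)$values,
               full$values[sub_ids, , drop = FALSE])
})

test_that("class totals give equal letters for indistinguishable time points", {
  # two time points with identical replicate sets: zero between-group
  # variance, within-group variance present
  m <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
              dimnames = list("c1", paste0("s", 1:6)))
  ann <- annotation_table("c1", "esters")
  design <- stage_design(paste0("s", 1:6), rep(c("S0", "S5"), each = 3),
                         rep(c("G1", "G4"), each = 3), rep(1:3, 2))
  res <- class_totals(feature_table(m, "concentration"), ann, design)
  expect_identical(unique(res$summary$letter), "a")
})

test_that("class totals separate clearly different time points", {
  # {1,1,1} vs {10,10,10} with tiny within-variance: letters a then b
  set.seed(1)
  m <- matrix(c(1, 1, 1, 10, 10, 10) + stats::rnorm(6, 0, 1e-6), nrow = 1,
              dimnames = list("c1", paste0("s", 1:6)))
  ann <- annotation_table("c1", "esters")
  design <- stage_design(paste0("s", 1:6), rep(c("S0", "S5"), each = 3),
                         rep(c("G1", "G4"), each = 3), rep(1:3, 2))
  res <- class_totals(feature_table(m, "concentration"), ann, design)
  lt <- res$summary$letter[order(res$summary$time_point)]
  expect_identical(lt, c("a", "b"))
})

test_that("three-group letters match an independent Tukey oracle", {
  # means 0.01, 0.02, 10 with sd 0.5, n = 6: the two small groups share
  # a letter, the large one differs (verified against TukeyHSD p-values
  # computed directly below)
  set.seed(7)
  y <- c(stats::rnorm(6, 0.01, 0.5), stats::rnorm(6, 0.02, 0.5),
         stats::rnorm(6, 10, 0.5))
  y <- abs(y)    # concentrations are non-negative
  m <- matrix(y, nrow = 1, dimnames = list("c1", paste0("s", 1:18)))
  tps <- rep(c("S0", "S2", "S5"), each = 6)
  design <- stage_design(paste0("s", 1:18), tps,
                         rep(c("G1", "G2", "G4"), each = 6), rep(1:6, 3))
  ann <- annotation_table("c1", "ketones")
  res <- class_totals(feature_table(m, "concentration"), ann, design)
  letters_by_tp <- stats::setNames(res$summary$letter, res$summary$time_point)
  # oracle: pairwise Tukey p-values straight from stats::TukeyHSD
  oracle <- stats::TukeyHSD(stats::aov(y ~ factor(tps)))[[1]][, "p adj"]
  expect_gt(oracle[["S2-S0"]], 0.05)
  expect_lt(oracle[["S5-S0"]], 0.05)
  expect_identical(letters_by_tp[["S0"]], letters_by_tp[["S2"]])
  expect_false(letters_by_tp[["S5"]] %in%
                 c(letters_by_tp[["S0"]], letters_by_tp[["S2"]]))
})

test_that("letter display shares a letter exactly when Tukey p >= alpha", {
  # property over random instances: reconstruct the share/differ relation
  # from the letter strings and compare with the p-value matrix
  for (seed in 1:8) {
    set.seed(seed)
    g <- rep(paste0("t", 1:4), each = 4)
    y <- stats::rnorm(16, mean = rep(sample(c(0, 0.5, 2, 4)), each = 4))
    tk <- stats::TukeyHSD(stats::aov(y ~ factor(g)))[[1]]
    lv <- paste0("t", 1:4)
    pmat <- matrix(1, 4, 4, dimnames = list(lv, lv))
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pmat[pairs] <- tk[, "p adj"]
    pmat[pairs[, 2:1]] <- tk[, "p adj"]
    cld <- cld_insert_absorb(pmat, alpha = 0.05,
                             means = tapply(y, g, mean))
    share <- outer(lv, lv, Vectorize(function(a, b)
      length(intersect(strsplit(cld[[a]], "")[[1]],
                       strsplit(cld[[b]], "")[[1]])) > 0))
    dimnames(share) <- list(lv, lv)
    for (a in lv) for (b in lv) if (a != b)
      expect_identical(share[a, b], pmat[a, b] >= 0.05)
  }
})

test_that("letters form a contiguous alphabet starting at a", {
  ds <- quick_dataset(seed = 4)
  ct <- fill_missing(semi_quantify(ds$ft, ds$isp))
  res <- class_totals(ct, ds$ann, ds$design)
  for (cl in unique(res$summary$compound_class)) {
    used <- sort(unique(unlist(strsplit(
      res$summary$letter[res$summary$compound_class == cl], ""))))
    expect_identical(used, letters[seq_along(used)])
  }
})

test_that("a single replicate in a time point is refused", {
  m <- matrix(1:5, nrow = 1, dimnames = list("c1", paste0("s", 1:5)))
  ann <- annotation_table("c1", "esters")
  design <- stage_design(paste0("s", 1:5),
                         c("S0", "S0", "S5", "S5", "S3"),
                         c("G1", "G1", "G4", "G4", "G4"),
                         c(1, 2, 1, 2, 1))
  expect_error(class_totals(feature_table(m, "concentration"), ann, design),
               "2 replicates")
})
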