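test_that("duplicated samples get identical PCA scores", {
  set.seed(1)
  X <- matrix(stats::rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("c", 1:8)))
  X2 <- rbind(X, X[3, , drop = FALSE])
  rownames(X2)[6] <- "s3dup"
  res <- pca(X2, scaling = "none")
  expect_equal(res$scores["s3", ], res$scores["s3dup", ], tolerance = 1e-10)
})

test_that("perfectly correlated variables give a rank-1 PCA", {
  x <- 1:10
  X <- cbind(x = as.numeric(x), y = as.numeric(x))
  rownames(X) <- paste0("s", 1:10)
  res <- pca(X, scaling = "uv")
  expect_equal(res$explained_variance_ratio[1], 1, tolerance = 1e-9)
})

test_that("explained variance matches an independent eigendecomposition", {
  set.seed(42)
  X <- matrix(stats::rnorm(6 * 20), 6, 20,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:20)))
  res <- pca(X, scaling = "uv")
  # oracle: eigenvalues of the covariance matrix of the scaled data
  Xs <- scale(X)
  ev <- eigen(stats::cov(Xs), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(res$explained_variance_ratio,
               ev / sum(ev), tolerance = 1e-8)
})

test_that("PCA scores are column-orthogonal and variance ratios valid", {
  set.seed(3)
  X <- matrix(stats::rnorm(10 * 15), 10, 15,
              dimnames = list(paste0("s", 1:10), paste0("c", 1:15)))
  res <- pca(X, scaling = "uv")
  G <- crossprod(res$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  evr <- res$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-9)
  # constant column under UV scaling points at the scaling policy
  X[, 1] <- 5
  expect_error(pca(X, scaling = "uv"), "scaling")
})

test_that("a single perfectly separating compound dominates the model", {
  # univariate closed form: when the separator carries all the in-sample
  # covariance with the labels, the predictive component is that column
  # and R2Y = 1; enforce the premise by residualising the noise columns
  # against the class contrast
  set.seed(5)
  n <- 12
  yc <- rep(c(-1, 1), each = n / 2)
  noise <- matrix(stats::rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("noise", 1:20)))
  noise <- apply(noise, 2, function(col) stats::resid(stats::lm(col ~ yc)))
  X <- cbind(sep = rep(c(0, 1), each = n / 2), noise)
  rownames(X) <- paste0("s", 1:n)
  y <- rep(c("A", "B"), each = n / 2)
  m <- opls_da(X, y, n_ortho = 1, cv_folds = 4, seed = 1)
  expect_gte(m$R2Y, 0.99)
  expect_identical(names(which.max(m$vip)), "sep")
})

test_that("VIP normalisation holds on every fitted model", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(stats::rnorm(14 * 30), 14, 30,
                dimnames = list(NULL, paste0("c", 1:30)))
    y <- rep(c("A", "B"), each = 7)
    m <- opls_da(X, y, n_ortho = 1, cv_folds = 0, seed = seed)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
  }
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(8)
  X <- matrix(stats::rnorm(16 * 25), 16, 25,
              dimnames = list(NULL, paste0("c", 1:25)))
  X[, 1:5] <- X[, 1:5] + rep(c(0, 2), each = 8)
  y <- rep(c("A", "B"), each = 8)
  m <- opls_da(X, y, n_ortho = 2, cv_folds = 0, seed = 1)
  for (a in seq_len(ncol(m$scores_ortho)))
    expect_lt(abs(stats::cor(m$scores, m$scores_ortho[, a])), 1e-8)
})

test_that("zero orthogonal components reproduce plain PLS1 exactly", {
  set.seed(9)
  X <- matrix(stats::rnorm(12 * 18), 12, 18,
              dimnames = list(paste0("s", 1:12), paste0("c", 1:18)))
  y <- rep(c("A", "B"), each = 6)
  m <- opls_da(X, y, n_ortho = 0, cv_folds = 0, seed = 1)
  # independent single-component PLS1 oracle on the scaled data
  Xs <- scale(X)
  yc <- rep(c(-1, 1), each = 6)
  w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(Xs %*% w)
  q <- sum(yc * t) / sum(t^2)
  expect_equal(unname(predict(m, X)), unname(q * t), tolerance = 1e-10)
  expect_equal(m$R2Y, 1 - sum((yc - q * t)^2) / sum(yc^2),
               tolerance = 1e-10)
})

test_that("Q2 never exceeds R2Y on synthetic datasets", {
  for (seed in c(2, 5, 11)) {
    ds <- quick_dataset(seed = seed)
    ct <- fill_missing(semi_quantify(ds$ft, ds$isp))
    sa <- ds$design$sample_id[ds$design$stage == "G1"]
    sb <- ds$design$sample_id[ds$design$stage == "G4"]
    X <- t(ct$values[, c(sa, sb)])
    y <- rep(c("G1", "G4"), c(length(sa), length(sb)))
    m <- opls_da(X, y, n_ortho = 1, cv_folds = 7, seed = seed)
    expect_lte(m$Q2, m$R2Y)
  }
})

test_that("classes that are too small are refused", {
  X <- matrix(stats::rnorm(5 * 4), 5, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  expect_error(opls_da(X, c("A", "A", "B", "B", "B")), "3 samples")
  expect_error(opls_da(X, rep("A", 5)), "two classes")
})

test_that("permutation p-value hits the formula floor on separable data", {
  ds <- generate_dataset(synth_config_strong(n_compounds = 60, n_key_up = 2,
                                             n_key_down = 1, seed = 21))
  ct <- fill_missing(semi_quantify(ds$ft, ds$isp))
  sa <- ds$design$sample_id[ds$design$stage == "G1"]
  sb <- ds$design$sample_id[ds$design$stage == "G4"]
  X <- t(ct$values[, c(sa, sb)])
  y <- rep(c("G1", "G4"), each = 12)
  pr <- permutation_test(X, y, n_perm = 19, seed = 4)
  expect_equal(pr$p_Q2, 1 / 20)
  expect_equal(pr$p_R2Y, 1 / 20)
  expect_true(all(pr$perm_Q2 < pr$observed["Q2"]))
  # identical seed reproduces the whole permutation stream
  pr2 <- permutation_test(X, y, n_perm = 19, seed = 4)
  expect_identical(pr$perm_Q2, pr2$perm_Q2)
  expect_error(permutation_test(X, y, n_perm = 0), "n_perm")
})
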