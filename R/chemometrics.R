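#' Unit-variance scale a matrix
#'
#' Centers each column and divides by its standard deviation (n - 1
#' denominator).
#'
#' @param X numeric matrix, samples in rows.
#' @param allow_constant if `FALSE` (default) a constant column is an
#'   error; if `TRUE` constant columns are centered and left unscaled
#'   (they carry no variance and contribute nothing downstream).
#' @return The scaled matrix with attributes `center` and `scale`.
#' @export
uv_scale <- function(X, allow_constant = FALSE) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    if (!allow_constant)
      stop("constant column(s) under UV scaling: ",
           paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "),
           "; drop them or use pareto/none scaling", call. = FALSE)
    sds[sds == 0] <- 1
  }
  out <- sweep(sweep(X, 2, ctr), 2, sds, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  out
}

#' Principal component analysis by singular value decomposition
#'
#' Columns (compounds) are centered and optionally scaled (`uv`: unit
#' variance; `pareto`: divide by the square root of the standard
#' deviation; `none`), then decomposed by SVD. Scores are `U %*% D`,
#' loadings are `V`, and the explained-variance ratio of component `a`
#' is `d_a^2 / sum(d^2)`. Sign convention: the largest-magnitude loading
#' of each component is made positive, so results are reproducible
#' across runs and platforms.
#'
#' @param X numeric matrix, samples in rows, compounds in columns; no
#'   missing values (fill upstream with [fill_missing()]).
#' @param scaling `"uv"`, `"pareto"` or `"none"`.
#' @param n_components number of components to keep (default all).
#' @return A list of class `pca_result`: `scores` (sample x component),
#'   `loadings` (compound x component), `explained_variance_ratio`,
#'   `scaling`.
#' @export
pca <- function(X, scaling = c("uv", "pareto", "none"),
                n_components = NULL) {
  scaling <- match.arg(scaling)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("PCA needs at least 2 samples and 2 compounds", call. = FALSE)
  if (anyNA(X)) stop("PCA input must not contain missing values", call. = FALSE)
  Xc <- switch(scaling,
               uv = uv_scale(X),
               pareto = {
                 sds <- apply(X, 2, stats::sd)
                 if (any(sds == 0))
                   stop("constant column(s) under pareto scaling; ",
                        "drop them or use scaling = 'none'", call. = FALSE)
                 sweep(sweep(X, 2, colMeans(X)), 2, sqrt(sds), `/`)
               },
               none = sweep(X, 2, colMeans(X)))
  sv <- svd(Xc)
  keep <- seq_len(min(if (is.null(n_components)) Inf else n_components,
                      sum(sv$d > sv$d[1] * 1e-12)))
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(keep))
  loadings <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (a in seq_along(keep)) {
    imax <- which.max(abs(loadings[, a]))
    if (loadings[imax, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_along(keep)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(keep)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = d^2 / sum(sv$d^2),
                 scaling = scaling),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf("<pca_result> %d components; PC1 %.2f%%, PC2 %.2f%% of variance\n",
              length(evr), 100 * evr[1],
              if (length(evr) > 1) 100 * evr[2] else NA))
  invisible(x)
}

## ---- OPLS-DA core ----------------------------------------------------------

# NIPALS PLS1 with orthogonal signal correction (Trygg-Wold OSC).
# Xs: scaled matrix; yc: centered numeric response. Returns the fitted
# predictive component, orthogonal components, and the filtered matrix.
fit_opls_core <- function(Xs, yc, n_ortho) {
  Wo <- Po <- To <- NULL
  Xf <- Xs
  for (a in seq_len(n_ortho)) {
    w <- crossprod(Xf, yc)
    w <- w / sqrt(sum(w^2))
    t <- Xf %*% w
    p <- crossprod(Xf, t) / sum(t^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break      # no y-orthogonal variation left
    wo <- wo / nrm
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    Wo <- cbind(Wo, wo); To <- cbind(To, to); Po <- cbind(Po, po)
  }
  w <- crossprod(Xf, yc)
  w <- w / sqrt(sum(w^2))
  t <- Xf %*% w
  p <- crossprod(Xf, t) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(w = drop(w), t = drop(t), p = drop(p), q = q,
       Wo = Wo, To = To, Po = Po, n_ortho_fitted = if (is.null(Wo)) 0 else ncol(Wo))
}

predict_opls_core <- function(core, Xnew_scaled) {
  Xf <- Xnew_scaled
  if (!is.null(core$Wo)) {
    for (a in seq_len(ncol(core$Wo))) {
      to <- Xf %*% core$Wo[, a]
      Xf <- Xf - to %*% t(core$Po[, a])
    }
  }
  drop(Xf %*% core$w) * core$q
}

# Encode a two-level grouping as -1/+1.
encode_binary_y <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2)
    stop("OPLS-DA needs exactly two classes, got ", nlevels(f), call. = FALSE)
  list(y = ifelse(as.integer(f) == 1L, -1, 1), levels = levels(f))
}

# Stratified fold assignment, seeded and reproducible.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis: a NIPALS
#' PLS1 regression of the centered -1/+1 class vector on the
#' UV-scaled matrix, with variation orthogonal to the class direction
#' removed into `n_ortho` separate components (Trygg-Wold orthogonal
#' signal correction) before the single predictive component is fitted.
#' Reports `R2Y` (fraction of class-label variance explained on the
#' training data), `Q2` (the cross-validated analogue, from seeded
#' stratified k-fold CV in which scaling and the full model are refitted
#' within each training split), and per-compound VIP scores from the
#' predictive component, normalised so that `mean(VIP^2) = 1`;
#' compounds with VIP >= 1 are more influential than average.
#'
#' @param X numeric matrix, samples in rows, compounds in columns; raw
#'   (unscaled) values — UV scaling is applied internally.
#' @param y two-level class labels, one per row of `X`; each class needs
#'   at least 3 samples.
#' @param n_ortho number of orthogonal components (default 1; 0 gives
#'   plain PLS1).
#' @param cv_folds folds for Q2 cross-validation (default 7, the
#'   conventional choice); 0 skips cross-validation and reports
#'   `Q2 = NA`.
#' @param seed integer seed for the fold assignment.
#' @return A list of class `opls_da_model`: predictive `scores`,
#'   `loadings`, `weights`, orthogonal `scores_ortho`/`loadings_ortho`,
#'   `R2Y`, `Q2`, `vip`, plus the scaling parameters and class levels.
#' @export
opls_da <- function(X, y, n_ortho = 1, cv_folds = 7, seed = 1) {
  enc <- encode_binary_y(y)
  if (min(table(enc$y)) < 3)
    stop("each class needs at least 3 samples for OPLS-DA with CV",
         call. = FALSE)
  Xs <- uv_scale(X, allow_constant = TRUE)
  yc <- enc$y - mean(enc$y)
  core <- fit_opls_core(Xs, yc, n_ortho)
  ss_tot <- sum(yc^2)
  r2y <- 1 - sum((yc - core$q * core$t)^2) / ss_tot

  ## VIP, predictive component only: vip_j = sqrt(K * w_j^2) (||w|| = 1)
  K <- ncol(X)
  vip <- sqrt(K) * abs(core$w)
  names(vip) <- colnames(X)

  ## Q2 from stratified k-fold CV, full refit (incl. scaling) per fold;
  ## cv_folds = 0 skips cross-validation (Q2 = NA)
  if (cv_folds >= 2) {
  folds <- stratified_folds(enc$y, cv_folds, seed)
  press <- 0
  for (f in seq_len(cv_folds)) {
    tr <- folds != f; te <- !tr
    if (!any(te)) next
    Xtr <- uv_scale(X[tr, , drop = FALSE], allow_constant = TRUE)
    ytr <- enc$y[tr]; ytr_c <- ytr - mean(ytr)
    core_f <- fit_opls_core(Xtr, ytr_c, n_ortho)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, attr(Xtr, "center")),
                 2, attr(Xtr, "scale"), `/`)
    yhat <- predict_opls_core(core_f, Xte) + mean(ytr)
    press <- press + sum((enc$y[te] - yhat)^2)
  }
  q2 <- 1 - press / ss_tot
  } else q2 <- NA_real_

  structure(list(scores = core$t, loadings = core$p, weights = core$w,
                 q = core$q,
                 scores_ortho = core$To, loadings_ortho = core$Po,
                 weights_ortho = core$Wo,
                 n_ortho = core$n_ortho_fitted,
                 R2Y = r2y, Q2 = q2, vip = vip,
                 center = attr(Xs, "center"), scale = attr(Xs, "scale"),
                 y_levels = enc$levels, y = enc$y, y_mean = mean(enc$y),
                 cv_folds = cv_folds, seed = seed),
            class = "opls_da_model")
}

#' @export
print.opls_da_model <- function(x, ...) {
  cat(sprintf("<opls_da_model> %s vs %s: 1 predictive + %d orthogonal; R2Y = %.4f, Q2 = %.4f\n",
              x$y_levels[1], x$y_levels[2], x$n_ortho, x$R2Y, x$Q2))
  invisible(x)
}

#' Predict class scores from a fitted OPLS-DA model
#'
#' @param object an `opls_da_model`.
#' @param newdata matrix with the same columns as the training matrix.
#' @param ... unused.
#' @return Numeric predicted y on the -1/+1 scale.
#' @export
predict.opls_da_model <- function(object, newdata, ...) {
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  core <- list(w = object$weights, q = object$q,
               Wo = object$weights_ortho, Po = object$loadings_ortho)
  predict_opls_core(core, Xs) + object$y_mean
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the full model (including cross-validation) under `n_perm`
#' uniform random permutations of the class labels and reports the
#' permuted R2Y and Q2 distributions together with empirical p-values
#' `p = (1 + #{perm >= observed}) / (n_perm + 1)`. A model whose
#' observed Q2 exceeds every permuted Q2 attains the formula floor
#' `1 / (n_perm + 1)`.
#'
#' @param X,y,n_ortho,cv_folds as in [opls_da()].
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed; drives both the fold assignment and the
#'   permutation stream.
#' @return A list of class `permutation_result`: `observed` (R2Y, Q2),
#'   `perm_R2Y`, `perm_Q2`, `p_R2Y`, `p_Q2`, `n_perm`.
#' @export
permutation_test <- function(X, y, n_ortho = 1, cv_folds = 7,
                             n_perm = 200, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  obs <- opls_da(X, y, n_ortho = n_ortho, cv_folds = cv_folds, seed = seed)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample(length(y)), simplify = FALSE)
  perm_r2y <- perm_q2 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yb <- y[perm_idx[[b]]]
    mb <- opls_da(X, yb, n_ortho = n_ortho, cv_folds = cv_folds,
                  seed = seed + b)
    perm_r2y[b] <- mb$R2Y
    perm_q2[b] <- mb$Q2
  }
  structure(list(observed = c(R2Y = obs$R2Y, Q2 = obs$Q2),
                 perm_R2Y = perm_r2y, perm_Q2 = perm_q2,
                 p_R2Y = (1 + sum(perm_r2y >= obs$R2Y)) / (n_perm + 1),
                 p_Q2 = (1 + sum(perm_q2 >= obs$Q2)) / (n_perm + 1),
                 n_perm = n_perm, model = obs),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations; observed R2Y = %.4f (p = %.4g), Q2 = %.4f (p = %.4g)\n",
              x$n_perm, x$observed["R2Y"], x$p_R2Y,
              x$observed["Q2"], x$p_Q2))
  invisible(x)
}
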