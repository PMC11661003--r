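#' Family-structure-respecting permutation of subject indices
#'
#' Returns a permutation `p` (use as `Y[p, ]`) in which whole families are
#' exchanged only with families of identical size, and members are shuffled
#' within each family (exchangeability-block style).  For an all-singleton
#' cohort this reduces to an unrestricted permutation.  Within-family
#' dependence is thereby preserved under the null.
#'
#' @param family_id length-N vector of family labels.
#' @param rng_seed optional integer seed; `NULL` (default) uses the current
#'   RNG state, so loops can draw many permutations from one seeding.
#' @return integer permutation of `1:N`.
#' @export
family_aware_permutation <- function(family_id, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  groups <- split(seq_along(family_id), family_id)
  sizes <- lengths(groups)
  p <- integer(length(family_id))
  for (s in unique(sizes)) {
    fams <- which(sizes == s)
    src <- if (length(fams) > 1L) fams[sample.int(length(fams))] else fams
    for (j in seq_along(fams)) {
      members <- groups[[src[j]]]
      if (s > 1L) members <- members[sample.int(s)]
      p[groups[[fams[j]]]] <- members
    }
  }
  p
}

new_permutation_result <- function(observed, null_values, n_perm,
                                   corrected_alpha) {
  structure(list(
    observed = observed, null_values = null_values,
    p_value = (1 + sum(null_values >= observed)) / (1 + n_perm),
    n_perm = as.integer(n_perm), corrected_alpha = corrected_alpha
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %.3f, p = %.4g (%d permutations, corrected alpha = %.4g)\n",
              x$observed, x$p_value, x$n_perm, x$corrected_alpha))
  invisible(x)
}

#' Discovery-phase permutation test for one outer split
#'
#' Breaks the X-Y association under the null by shuffling the rows of the Y
#' block -- family-aware, separately within the optimization and test sets
#' (families never straddle a split, so both sides can be shuffled within
#' themselves).  Per iteration the RCCA model is refitted on the permuted
#' optimization set with the hyperparameters selected on the unpermuted data,
#' the permuted test set is projected onto the resulting weights, and the
#' test canonical correlation is recorded.  One-sided p-value with the
#' `(1 + k) / (1 + n_perm)` convention; the Bonferroni-corrected threshold
#' `alpha / n_comparisons` (default: over the 5 outer splits) is stored
#' alongside.
#'
#' Deconfounding (optimization-set betas) and prior-dimension deflation are
#' applied before permuting; row permutation commutes with projection
#' deflation and leaves column statistics unchanged, so covariances that do
#' not involve the permuted rows are computed once outside the loop.
#'
#' @param X,Y raw (confounded) data matrices for the whole cohort.
#' @param confounds N x C confound matrix.
#' @param family_id family labels for the whole cohort.
#' @param optimization_idx,test_idx row indices of the outer split.
#' @param cx,cy the selected regularization pair.
#' @param prior_models deflation chain for this split (possibly empty).
#' @param seed_cols seed-column indices of `Y` (sign convention).
#' @param n_perm number of permutations (default 1000).
#' @param rng_seed integer seed.
#' @param alpha nominal level before correction.
#' @param n_comparisons Bonferroni divisor (default 5 outer splits).
#' @return a `permutation_result`.
#' @export
permutation_test_discovery <- function(X, Y, confounds, family_id,
                                       optimization_idx, test_idx, cx, cy,
                                       prior_models = list(), seed_cols = NULL,
                                       n_perm = 1000L, rng_seed = 1L,
                                       alpha = 0.05, n_comparisons = 5L) {
  if (n_perm < 1L)
    stop_mb("n_perm must be >= 1", class = "mbrcca_value_error")
  dec <- deconfound_partitions(X, Y, confounds, optimization_idx,
                               list(test = test_idx))
  dop <- deflate_chain(dec$X_train, dec$Y_train, prior_models)
  dte <- deflate_chain(dec$X_test, dec$Y_test, prior_models)

  model <- fit_rcca(dop$X, dop$Y, cx, cy, seed_cols = seed_cols)
  observed <- rcca_transform(model, dte$X, dte$Y)$canonical_correlation

  xs <- list(center = model$x_center, scale = model$x_scale)
  ys <- list(center = model$y_center, scale = model$y_scale)
  Xs_o <- standardize_cols(dop$X, xs); Ys_o <- standardize_cols(dop$Y, ys)
  Xs_t <- standardize_cols(dte$X, xs); Ys_t <- standardize_cols(dte$Y, ys)
  n_opt <- nrow(Xs_o)
  Sxx <- crossprod(Xs_o) / (n_opt - 1)
  Syy <- crossprod(Ys_o) / (n_opt - 1)
  Ax <- shrunken_inv_sqrt(Sxx, cx)
  Ay <- shrunken_inv_sqrt(Syy, cy)
  fam_o <- family_id[optimization_idx]
  fam_t <- family_id[test_idx]

  set.seed(rng_seed)
  null_values <- vapply(seq_len(n_perm), function(b) {
    po <- family_aware_permutation(fam_o)
    pt <- family_aware_permutation(fam_t)
    Sxy <- crossprod(Xs_o, Ys_o[po, , drop = FALSE]) / (n_opt - 1)
    sv <- svd(Ax %*% Sxy %*% Ay, nu = 1L, nv = 1L)
    u <- drop(Ax %*% sv$u[, 1L]); v <- drop(Ay %*% sv$v[, 1L])
    cor(drop(Xs_t %*% u), drop(Ys_t[pt, , drop = FALSE] %*% v))
  }, numeric(1L))

  new_permutation_result(observed, null_values, n_perm,
                         alpha / n_comparisons)
}

#' Validation-phase permutation test
#'
#' Tests whether the canonical correlation obtained by projecting the
#' validation cohort's evaluation subset ("validation dataset 2") onto
#' discovery weights exceeds chance.  Per iteration the Y rows are shuffled
#' independently within the discovery optimization set (family-aware) and
#' within the evaluation subset; the model is refitted on the permuted
#' optimization set with the fixed hyperparameters and the permuted
#' evaluation subset is projected onto the refitted weights.
#'
#' @param X_opt,Y_opt discovery optimization-set matrices, already
#'   deconfounded and chain-deflated (the space the dimension was fitted in).
#' @param family_id_opt family labels of the optimization subjects.
#' @param cx,cy the selected regularization pair.
#' @param X_val,Y_val validation evaluation matrices: deconfounded via the
#'   estimation/evaluation split, standardized with estimation-subset
#'   statistics, and chain-deflated with the discovery models.
#' @param family_id_val family labels of the evaluation subjects (default
#'   singletons).
#' @param seed_cols seed-column indices of `Y` (sign convention).
#' @param n_perm,rng_seed,alpha as in [permutation_test_discovery()].
#' @return a `permutation_result` (no Bonferroni divisor: one test per
#'   validated dimension; `corrected_alpha = alpha`).
#' @export
permutation_test_validation <- function(X_opt, Y_opt, family_id_opt, cx, cy,
                                        X_val, Y_val, family_id_val = NULL,
                                        seed_cols = NULL, n_perm = 1000L,
                                        rng_seed = 1L, alpha = 0.05) {
  if (n_perm < 1L)
    stop_mb("n_perm must be >= 1", class = "mbrcca_value_error")
  family_id_val <- family_id_val %||% seq_len(nrow(X_val))
  model <- fit_rcca(X_opt, Y_opt, cx, cy, seed_cols = seed_cols)
  observed <- cor(drop(X_val %*% model$u), drop(Y_val %*% model$v))

  xs <- list(center = model$x_center, scale = model$x_scale)
  ys <- list(center = model$y_center, scale = model$y_scale)
  Xs_o <- standardize_cols(X_opt, xs); Ys_o <- standardize_cols(Y_opt, ys)
  n_opt <- nrow(Xs_o)
  Ax <- shrunken_inv_sqrt(crossprod(Xs_o) / (n_opt - 1), cx)
  Ay <- shrunken_inv_sqrt(crossprod(Ys_o) / (n_opt - 1), cy)

  set.seed(rng_seed)
  null_values <- vapply(seq_len(n_perm), function(b) {
    po <- family_aware_permutation(family_id_opt)
    pv <- family_aware_permutation(family_id_val)
    Sxy <- crossprod(Xs_o, Ys_o[po, , drop = FALSE]) / (n_opt - 1)
    sv <- svd(Ax %*% Sxy %*% Ay, nu = 1L, nv = 1L)
    u <- drop(Ax %*% sv$u[, 1L]); v <- drop(Ay %*% sv$v[, 1L])
    cor(drop(X_val %*% u), drop(Y_val[pv, , drop = FALSE] %*% v))
  }, numeric(1L))

  new_permutation_result(observed, null_values, n_perm, alpha)
}
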