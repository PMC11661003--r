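#' Project a cohort onto discovery weights
#'
#' Applies a discovery-phase deflation chain and projects the data onto the
#' final model's weights, yielding scores, loadings and the canonical
#' correlation in the projected cohort ("the canonical correlation serves as
#' an effect size" for generalizability).
#'
#' @param models a single `rcca_model` or the list of chained models for the
#'   target dimension (dimension 1 .. d, in order); the last model is the
#'   dimension being projected, the head of the list is applied as deflation.
#' @param X,Y data for the cohort being projected, deconfounded.  With
#'   `standardize = TRUE` the discovery models' fit-time statistics are used;
#'   with `standardize = FALSE` the caller supplies already-standardized data
#'   (cross-cohort policy: standardization statistics from the validation
#'   cohort's confound-estimation subset).
#' @param standardize see above.
#' @return a `latent_dimension_report`.
#' @export
project_cohort <- function(models, X, Y, standardize = TRUE) {
  if (inherits(models, "rcca_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1L), "rcca_model")))
  head_models <- models[-length(models)]
  if (length(head_models)) {
    out <- deflate_chain(X, Y, head_models, standardize = standardize)
    X <- out$X; Y <- out$Y
    ## after a discovery-standardized deflation the data already live in the
    ## chain's standardized space; after a caller-standardized chain they stay
    ## in the caller's space
    standardize_last <- standardize
  } else {
    standardize_last <- standardize
  }
  rcca_transform(models[[length(models)]], X, Y, standardize = standardize_last)
}

#' Pearson similarity of multiblock loadings across cohorts
#'
#' @param a,b loading vectors of equal length (>= 3).
#' @return list with Pearson `r` and two-sided `p`.
#' @export
compare_multiblock_loadings <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop_mb("loading vectors must have equal length >= 3",
            class = "mbrcca_contract_error")
  if (sd(a) == 0 || sd(b) == 0)
    stop_mb("correlation undefined: zero-variance loading vector",
            class = "mbrcca_value_error")
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spatially adjusted similarity of brain loadings across cohorts
#'
#' Partial Pearson correlation of two brain-loading maps controlling for a
#' spatial covariate (by default the per-parcel mean grey-matter volume of
#' the discovery cohort), computed by correlating the OLS residuals of each
#' map regressed on the covariate.  Significance comes from a permutation of
#' parcel labels rather than the analytic t distribution, to stay robust to
#' residual spatial structure; two-sided on `|partial r|`.
#'
#' @param a,b brain loading vectors of equal length.
#' @param spatial_covariate per-parcel covariate of the same length.
#' @param n_perm parcel-label permutations (default 1000).
#' @param rng_seed integer seed.
#' @return list with `partial_r`, permutation `p` and the null vector.
#' @export
compare_brain_loadings <- function(a, b, spatial_covariate, n_perm = 1000L,
                                   rng_seed = 1L) {
  if (length(a) != length(b) || length(a) != length(spatial_covariate))
    stop_mb("loading vectors and spatial covariate must have equal length",
            class = "mbrcca_contract_error")
  resid_on <- function(y, x) {
    f <- qr(cbind(1, x))
    y - cbind(1, x) %*% qr.coef(f, y)
  }
  ra <- drop(resid_on(a, spatial_covariate))
  rb <- drop(resid_on(b, spatial_covariate))
  if (sd(ra) < 1e-14 || sd(rb) < 1e-14)
    stop_mb("partial correlation undefined: zero residual variance",
            class = "mbrcca_value_error")
  partial_r <- cor(ra, rb)
  set.seed(rng_seed)
  null_values <- vapply(seq_len(n_perm), function(i) {
    cor(ra, drop(resid_on(b[sample.int(length(b))], spatial_covariate)))
  }, numeric(1L))
  p <- (1 + sum(abs(null_values) >= abs(partial_r))) / (1 + n_perm)
  list(partial_r = partial_r, p = p, null_values = null_values)
}
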