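#' Fit a regularized CCA model for one latent dimension
#'
#' Finds weight vectors `u` (brain) and `v` (multiblock) maximizing the
#' correlation-type objective `t(u) %*% Sxy %*% v` subject to the shrunken
#' unit-variance constraints `t(u) %*% Rx %*% u = 1` with
#' `Rx = (1 - cx) * Sxx + cx * I` (analogously for `v`).  `cx = cy = 0`
#' recovers classical CCA; `cx = cy = 1` recovers partial least squares
#' (the leading singular pair of the cross-covariance).  The solution is
#' obtained through shrunken whitening: the leading singular pair of
#' `K = Rx^{-1/2} %*% Sxy %*% Ry^{-1/2}` mapped back through the whitening
#' transforms.
#'
#' Columns of `X` and `Y` are z-scored internally using the statistics of the
#' data supplied here; those statistics are stored in the model and re-used
#' when projecting held-out data, so no information flows from test data into
#' the fit.  Covariances use the `n - 1` denominator.
#'
#' The sign ambiguity of the singular pair is resolved by requiring the
#' largest-magnitude entry of `v` among the seed columns (`seed_cols`,
#' default: all of `Y`) to be positive, so that weights are comparable across
#' refits and across cohorts.
#'
#' @param X numeric matrix (subjects x brain parcels), deconfounded.
#' @param Y numeric matrix (subjects x multiblock variables), deconfounded.
#' @param cx,cy regularization parameters in `[0, 1]`.
#' @param seed_cols integer indices of `Y` columns holding the seed block,
#'   used only for the sign convention.
#' @param dimension_index 1-based index of the latent dimension this model
#'   represents (informational).
#' @return an object of class `rcca_model` with elements `u`, `v`, `cx`,
#'   `cy`, `train_canonical_correlation`, the fit-time standardization
#'   statistics, and `dimension_index`.
#' @seealso [rcca_transform()], [rcca_deflate()]
#' @export
fit_rcca <- function(X, Y, cx, cy, seed_cols = NULL, dimension_index = 1L) {
  X <- as_num_matrix(X, "X"); Y <- as_num_matrix(Y, "Y")
  check_finite(X, "X"); check_finite(Y, "Y")
  if (nrow(X) != nrow(Y))
    stop_mb("X and Y must have the same number of rows (%d vs %d)",
            nrow(X), nrow(Y), class = "mbrcca_contract_error")
  for (c_ in c(cx = cx, cy = cy))
    if (!is.finite(c_) || c_ < 0 || c_ > 1)
      stop_mb("regularization parameters must lie in [0, 1]",
              class = "mbrcca_value_error")
  n <- nrow(X)
  if (n < 3L)
    stop_mb("need at least 3 subjects to fit", class = "mbrcca_value_error")
  seed_cols <- seed_cols %||% seq_len(ncol(Y))

  xs <- col_stats(X); ys <- col_stats(Y)
  Xs <- standardize_cols(X, xs); Ys <- standardize_cols(Y, ys)

  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)

  Ax <- shrunken_inv_sqrt(Sxx, cx)
  Ay <- shrunken_inv_sqrt(Syy, cy)
  K  <- Ax %*% Sxy %*% Ay
  sv <- svd(K, nu = 1L, nv = 1L)
  u  <- drop(Ax %*% sv$u[, 1L])
  v  <- drop(Ay %*% sv$v[, 1L])

  ## sign convention: largest-magnitude seed entry of v is positive
  j <- seed_cols[which.max(abs(v[seed_cols]))]
  if (v[j] < 0) { u <- -u; v <- -v }

  sx <- drop(Xs %*% u); sy <- drop(Ys %*% v)
  structure(list(
    u = setNames(u, colnames(X)), v = setNames(v, colnames(Y)),
    cx = cx, cy = cy,
    train_canonical_correlation = cor(sx, sy),
    x_center = xs$center, x_scale = xs$scale,
    y_center = ys$center, y_scale = ys$scale,
    seed_cols = seed_cols, dimension_index = as.integer(dimension_index),
    n = n
  ), class = "rcca_model")
}

## pseudo inverse square root of the shrunken covariance (1-c) S + c I;
## eigenvalues below a relative floor are dropped (rank-deficient c = 0 case)
shrunken_inv_sqrt <- function(S, c_) {
  R <- (1 - c_) * S
  diag(R) <- diag(R) + c_
  e <- eigen(R, symmetric = TRUE)
  tol <- max(e$values, 0) * 1e-10
  keep <- e$values > tol
  if (!any(keep))
    stop_mb("shrunken covariance is numerically zero", class = "mbrcca_value_error")
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / sqrt(e$values[keep]))
}

#' Project data through a fitted RCCA model
#'
#' Computes brain scores `Xu`, multiblock scores `Yv`, their Pearson
#' correlation (the canonical correlation, the effect size reported
#' throughout), and loadings: the correlation of every original variable with
#' its own block's score (brain variables vs brain scores, multiblock
#' variables vs multiblock scores).
#'
#' @param model an `rcca_model`.
#' @param X,Y data in the same column order as at fit time.
#' @param standardize if `TRUE` (default) z-score with the model's fit-time
#'   statistics; `FALSE` assumes the caller already standardized (used for
#'   cross-cohort projection where standardization statistics come from the
#'   validation cohort's confound-estimation subset).
#' @return a `latent_dimension_report`: `brain_scores`, `multiblock_scores`,
#'   `brain_loadings`, `multiblock_loadings`, `canonical_correlation`.
#' @export
rcca_transform <- function(model, X, Y, standardize = TRUE) {
  X <- as_num_matrix(X, "X"); Y <- as_num_matrix(Y, "Y")
  check_model_columns(model, X, Y)
  Xs <- if (standardize) standardize_cols(X, list(center = model$x_center, scale = model$x_scale)) else X
  Ys <- if (standardize) standardize_cols(Y, list(center = model$y_center, scale = model$y_scale)) else Y
  sx <- drop(Xs %*% model$u); sy <- drop(Ys %*% model$v)
  structure(list(
    brain_scores = sx, multiblock_scores = sy,
    brain_loadings = drop(cor(Xs, sx)),
    multiblock_loadings = drop(cor(Ys, sy)),
    canonical_correlation = cor(sx, sy),
    dimension_index = model$dimension_index
  ), class = "latent_dimension_report")
}

check_model_columns <- function(model, X, Y) {
  if (ncol(X) != length(model$u) || ncol(Y) != length(model$v))
    stop_mb("column count mismatch with the fitted model (X %d vs %d, Y %d vs %d)",
            ncol(X), length(model$u), ncol(Y), length(model$v),
            class = "mbrcca_contract_error")
  mismatch <- function(have, want) {
    if (is.null(have) || is.null(names(want))) return(character())
    have[have != names(want)]
  }
  bad <- c(mismatch(colnames(X), model$u), mismatch(colnames(Y), model$v))
  if (length(bad))
    stop_mb("column name mismatch with the fitted model: %s",
            paste(unique(bad), collapse = ", "), class = "mbrcca_contract_error")
  invisible(TRUE)
}

#' Projection deflation of a latent dimension
#'
#' Removes the rank-one component along each block's own score direction:
#' `X <- X - s (s's)^{-1} s' X` with `s = X u`, and analogously for `Y`.
#' Applied to the training partition this makes scores of a subsequent fit
#' orthogonal to the current scores; applied to held-out data it removes the
#' same direction using the training-fit weights and the partition's own
#' scores.  Input is standardized with the model's fit-time statistics (unless
#' `standardize = FALSE`) and the returned matrices live in that standardized
#' space, so chains of deflations are self-consistent: a model fitted on the
#' output stores the statistics of that space.
#'
#' @inheritParams rcca_transform
#' @return list with deflated matrices `X` and `Y`.
#' @export
rcca_deflate <- function(X, Y, model, standardize = TRUE) {
  X <- as_num_matrix(X, "X"); Y <- as_num_matrix(Y, "Y")
  check_model_columns(model, X, Y)
  Xs <- if (standardize) standardize_cols(X, list(center = model$x_center, scale = model$x_scale)) else X
  Ys <- if (standardize) standardize_cols(Y, list(center = model$y_center, scale = model$y_scale)) else Y
  list(X = deflate_one(Xs, model$u), Y = deflate_one(Ys, model$v))
}

deflate_one <- function(M, w) {
  s <- drop(M %*% w)
  ss <- sum(s^2)
  if (!is.finite(ss) || ss < 1e-12)
    stop_mb("degenerate latent dimension: score vector has (near) zero norm",
            class = "mbrcca_degenerate_error")
  M - s %*% (crossprod(s, M) / ss)
}

#' Apply a sequence of deflations
#'
#' Runs [rcca_deflate()] for each model in order, feeding each deflated pair
#' into the next.  The first model standardizes per `standardize`; later
#' models always use their stored statistics (they were fitted on the deflated
#' output of their predecessors).
#'
#' @param X,Y data matrices (deconfounded).
#' @param models list of `rcca_model`s in extraction order.
#' @param standardize `TRUE`: every model standardizes with its own fit-time
#'   statistics (discovery-space chaining); `FALSE`: no standardization
#'   anywhere (data already standardized by the caller's policy).
#' @return list with matrices `X` and `Y` after all deflations.
#' @export
deflate_chain <- function(X, Y, models, standardize = TRUE) {
  for (m in models) {
    out <- rcca_deflate(X, Y, m, standardize = standardize)
    X <- out$X; Y <- out$Y
  }
  list(X = X, Y = Y)
}

#' @export
print.rcca_model <- function(x, ...) {
  cat(sprintf("RCCA model (dimension %d): P = %d, R = %d, cx = %.3g, cy = %.3g\n",
              x$dimension_index, length(x$u), length(x$v), x$cx, x$cy))
  cat(sprintf("  training canonical correlation: %.3f (n = %d)\n",
              x$train_canonical_correlation, x$n))
  invisible(x)
}

#' @export
print.latent_dimension_report <- function(x, ...) {
  cat(sprintf("Latent dimension %s: canonical correlation %.3f (n = %d)\n",
              x$dimension_index %||% "?", x$canonical_correlation,
              length(x$brain_scores)))
  invisible(x)
}

#' Serialize / restore an RCCA model as JSON
#'
#' The JSON carries weights, regularization pair, standardization vectors and
#' the dimension index -- sufficient to project any new cohort.
#'
#' @param model an `rcca_model`.
#' @param path file path.
#' @export
write_rcca_model <- function(model, path) {
  payload <- unclass(model)
  payload$x_names <- names(model$u)
  payload$y_names <- names(model$v)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_rcca_model
#' @export
read_rcca_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$u <- setNames(unlist(m$u), m$x_names)
  m$v <- setNames(unlist(m$v), m$y_names)
  m$x_center <- setNames(unlist(m$x_center), m$x_names)
  m$x_scale <- setNames(unlist(m$x_scale), m$x_names)
  m$y_center <- setNames(unlist(m$y_center), m$y_names)
  m$y_scale <- setNames(unlist(m$y_scale), m$y_names)
  m$seed_cols <- as.integer(m$seed_cols)
  m$dimension_index <- as.integer(m$dimension_index)
  m$x_names <- m$y_names <- NULL
  structure(m, class = "rcca_model")
}
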