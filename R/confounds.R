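#' Fit a confound regression model on training data
#'
#' Ordinary least squares of every variable on the confounds (age,
#' age-squared, gender, TIV by convention -- any full-rank confound matrix is
#' accepted) with an intercept.  Residuals of the training data are exactly
#' orthogonal to the centered confound columns; the fitted coefficients are
#' the only thing carried to held-out data, so no information leaks from test
#' subjects into the deconfounding.
#'
#' @param data numeric matrix N x V of variables to deconfound.
#' @param confounds numeric matrix N x C of confounds (raw scale; an
#'   intercept is added internally).
#' @return object of class `confound_model`: `beta` ((C+1) x V, intercept
#'   first), `confound_means`, `variable_names`, `confound_names`,
#'   `fitted_on` (training N).
#' @export
fit_confound_model <- function(data, confounds) {
  data <- as_num_matrix(data, "data")
  confounds <- as_num_matrix(confounds, "confounds")
  if (nrow(data) != nrow(confounds))
    stop_mb("data and confounds must be row-aligned",
            class = "mbrcca_contract_error")
  D <- cbind(`(intercept)` = 1, confounds)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    dropped <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop_mb("confounds are rank-deficient after centering; collinear: %s",
            paste(dropped, collapse = ", "), class = "mbrcca_value_error")
  }
  beta <- qr.coef(qd, data)
  structure(list(beta = beta,
                 confound_means = colMeans(confounds),
                 variable_names = colnames(data),
                 confound_names = colnames(confounds),
                 fitted_on = nrow(data)),
            class = "confound_model")
}

#' Residualize data with a previously fitted confound model
#'
#' Applies training-set coefficients to new data: `data - [1, C] %*% beta`.
#' No refitting happens here; on held-out data the residuals are therefore
#' only approximately orthogonal to the confounds, which is the price of
#' avoiding train-test leakage.
#'
#' @param model a `confound_model`.
#' @param data numeric matrix with the same variables (order and names) as at
#'   fit time.
#' @param confounds numeric matrix with the fit-time confound columns.
#' @return residual matrix of the same shape as `data`.
#' @export
apply_confound_model <- function(model, data, confounds) {
  stopifnot(inherits(model, "confound_model"))
  data <- as_num_matrix(data, "data")
  confounds <- as_num_matrix(confounds, "confounds")
  if (ncol(data) != ncol(model$beta))
    stop_mb("variable count mismatch: model fitted on %d variables, data has %d",
            ncol(model$beta), ncol(data), class = "mbrcca_contract_error")
  if (!is.null(colnames(data)) && !is.null(model$variable_names) &&
      !identical(colnames(data), model$variable_names))
    stop_mb("variable name mismatch with the confound model",
            class = "mbrcca_contract_error")
  if (nrow(data) == 0L) return(data)
  data - cbind(1, confounds) %*% model$beta
}

## fit on the training rows of both blocks, residualize training and any
## number of held-out partitions; internal convenience used by the CV loops
deconfound_partitions <- function(X, Y, confounds, train_idx, other_idx = list()) {
  cmx <- fit_confound_model(X[train_idx, , drop = FALSE],
                            confounds[train_idx, , drop = FALSE])
  cmy <- fit_confound_model(Y[train_idx, , drop = FALSE],
                            confounds[train_idx, , drop = FALSE])
  res <- list(
    X_train = apply_confound_model(cmx, X[train_idx, , drop = FALSE],
                                   confounds[train_idx, , drop = FALSE]),
    Y_train = apply_confound_model(cmy, Y[train_idx, , drop = FALSE],
                                   confounds[train_idx, , drop = FALSE]),
    model_x = cmx, model_y = cmy)
  for (nm in names(other_idx)) {
    idx <- other_idx[[nm]]
    res[[paste0("X_", nm)]] <- apply_confound_model(
      cmx, X[idx, , drop = FALSE], confounds[idx, , drop = FALSE])
    res[[paste0("Y_", nm)]] <- apply_confound_model(
      cmy, Y[idx, , drop = FALSE], confounds[idx, , drop = FALSE])
  }
  res
}

#' Split a validation cohort for cross-cohort deconfounding
#'
#' Because the validation cohort's confound distribution (notably age) can
#' differ radically from the discovery cohort's, confound regressors from the
#' discovery phase cannot be reused.  Instead a random subset of
#' `n_estimation` subjects ("validation dataset 1") is set aside purely to
#' estimate confound regressors, which are then applied to the remaining
#' subjects ("validation dataset 2") on which all validation statistics are
#' computed.
#'
#' @param cohort a `multiblock_cohort`.
#' @param n_estimation subjects reserved for confound estimation (default
#'   200).
#' @param rng_seed integer seed; the partition is deterministic in it.
#' @return list with `multiblock_cohort`s `estimation` and `evaluation` and
#'   the index vectors `estimation_idx`, `evaluation_idx`.
#' @export
split_validation_for_deconfounding <- function(cohort, n_estimation = 200L,
                                               rng_seed = 1L) {
  stopifnot(inherits(cohort, "multiblock_cohort"))
  n <- length(cohort$subject_ids)
  if (n_estimation < 1L || n_estimation >= n)
    stop_mb("n_estimation must be in 1..(N-1); got %d with N = %d",
            n_estimation, n, class = "mbrcca_value_error")
  set.seed(rng_seed)
  est <- sort(sample.int(n, n_estimation))
  ev <- setdiff(seq_len(n), est)
  list(estimation = subset_cohort(cohort, est),
       evaluation = subset_cohort(cohort, ev),
       estimation_idx = est, evaluation_idx = ev)
}

#' Serialize / restore a confound model as JSON
#'
#' @param model a `confound_model`.
#' @param path file path.
#' @export
write_confound_model <- function(model, path) {
  jsonlite::write_json(
    list(beta = model$beta, confound_means = model$confound_means,
         variable_names = model$variable_names,
         confound_names = model$confound_names, fitted_on = model$fitted_on),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_confound_model
#' @export
read_confound_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- m$beta
  colnames(beta) <- m$variable_names
  rownames(beta) <- c("(intercept)", m$confound_names)
  structure(list(beta = beta,
                 confound_means = setNames(unlist(m$confound_means),
                                           m$confound_names),
                 variable_names = m$variable_names,
                 confound_names = m$confound_names,
                 fitted_on = as.integer(m$fitted_on)),
            class = "confound_model")
}
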