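#' Build a nested, family-respecting cross-validation plan
#'
#' Partitions subjects into `n_outer` outer folds (each fold serving once as
#' the test set, the remainder as the optimization set) and, within every
#' optimization set, into `n_inner` inner folds (training / validation).  All
#' members of a family always land on the same side of every split.  Fold
#' sizes are balanced by greedy bin packing of families (largest family
#' first, seeded random tie-breaking), which is deterministic under
#' `rng_seed` and adequate for HCP-like family-size distributions.
#'
#' @param family_id length-N vector of family labels (singletons allowed).
#' @param n_outer,n_inner numbers of outer and inner folds (defaults 5 and 5).
#' @param rng_seed integer seed.
#' @return object of class `split_plan`: `outer` (list of
#'   `list(optimization, test)` index vectors), `inner` (per outer split, a
#'   list of `list(training, validation)` index vectors), plus the inputs.
#' @export
build_split_plan <- function(family_id, n_outer = 5L, n_inner = 5L,
                             rng_seed = 1L) {
  groups <- split(seq_along(family_id), family_id)
  if (length(groups) < n_outer)
    stop_mb("need at least %d families for %d outer folds, have %d",
            n_outer, n_outer, length(groups), class = "mbrcca_value_error")
  outer_folds <- pack_groups(groups, n_outer, derive_seed(rng_seed, 0L))
  outer <- lapply(seq_len(n_outer), function(o)
    list(optimization = sort(unlist(outer_folds[-o], use.names = FALSE)),
         test = sort(outer_folds[[o]])))
  inner <- lapply(seq_len(n_outer), function(o) {
    opt_groups <- groups[vapply(groups, function(g)
      all(g %in% outer[[o]]$optimization), logical(1L))]
    if (length(opt_groups) < n_inner)
      stop_mb("outer split %d: need at least %d families in the optimization set",
              o, n_inner, class = "mbrcca_value_error")
    folds <- pack_groups(opt_groups, n_inner, derive_seed(rng_seed, o))
    lapply(seq_len(n_inner), function(i)
      list(training = sort(unlist(folds[-i], use.names = FALSE)),
           validation = sort(folds[[i]])))
  })
  structure(list(outer = outer, inner = inner, family_id = family_id,
                 n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 rng_seed = as.integer(rng_seed)),
            class = "split_plan")
}

## greedy family-size bin packing: biggest family goes to the currently
## smallest fold; seeded shuffle breaks ties deterministically
pack_groups <- function(groups, k, seed) {
  set.seed(seed)
  shuffled <- if (length(groups) > 1L) sample(seq_along(groups)) else 1L
  ord <- shuffled[order(lengths(groups)[shuffled], decreasing = TRUE)]
  fold_of <- integer(length(groups))
  fold_n <- integer(k)
  for (g in ord) {
    f <- which.min(fold_n)
    fold_of[g] <- f
    fold_n[f] <- fold_n[f] + length(groups[[g]])
  }
  lapply(seq_len(k), function(f)
    unlist(groups[fold_of == f], use.names = FALSE))
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d outer x %d inner folds over %d subjects (%d families)\n",
              x$n_outer, x$n_inner, length(x$family_id),
              length(unique(x$family_id))))
  cat("  outer test sizes:", vapply(x$outer, function(o) length(o$test), 1L), "\n")
  invisible(x)
}

#' Default regularization grid
#'
#' @return data frame of `(cx, cy)` pairs spanning the CCA (0) to PLS (1)
#'   interpolation.
#' @export
default_grid <- function() {
  v <- c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1)
  expand.grid(cx = v, cy = v)
}

normalize_grid <- function(grid) {
  if (is.matrix(grid)) grid <- as.data.frame(grid)
  if (is.list(grid) && !is.data.frame(grid) &&
      all(vapply(grid, length, 1L) == 2L))
    grid <- do.call(rbind.data.frame,
                    lapply(grid, function(p) list(cx = p[[1]], cy = p[[2]])))
  if (!is.data.frame(grid) || !all(c("cx", "cy") %in% names(grid)) ||
      nrow(grid) == 0L)
    stop_mb("grid must be a non-empty set of (cx, cy) pairs",
            class = "mbrcca_config_error")
  grid[, c("cx", "cy")]
}

## fast RCCA refit machinery for inner loops: covariances are computed once
## per fold, only the shrunken whitening and SVD depend on (cx, cy)
rcca_fold_cache <- function(X_train, Y_train, X_val, Y_val) {
  xs <- col_stats(X_train); ys <- col_stats(Y_train)
  Xs <- standardize_cols(X_train, xs); Ys <- standardize_cols(Y_train, ys)
  n <- nrow(Xs)
  list(Xs = Xs, Ys = Ys, xs = xs, ys = ys, n = n,
       Sxx = crossprod(Xs) / (n - 1), Syy = crossprod(Ys) / (n - 1),
       Sxy = crossprod(Xs, Ys) / (n - 1),
       Xv = standardize_cols(X_val, xs), Yv = standardize_cols(Y_val, ys))
}

rcca_pair_cached <- function(cache, cx, cy) {
  Ax <- shrunken_inv_sqrt(cache$Sxx, cx)
  Ay <- shrunken_inv_sqrt(cache$Syy, cy)
  sv <- svd(Ax %*% cache$Sxy %*% Ay, nu = 1L, nv = 1L)
  list(u = drop(Ax %*% sv$u[, 1L]), v = drop(Ay %*% sv$v[, 1L]))
}

#' Hyperparameter search over a nested split plan
#'
#' For every outer split: each `(cx, cy)` pair is fitted on each inner
#' training fold (after deconfounding with that fold's own training betas and
#' applying any prior-dimension deflations) and scored by canonical
#' correlation on the inner validation fold.  Per pair the inner folds are
#' aggregated into a mean validation correlation and a stability score (mean
#' pairwise Pearson correlation of sign-aligned multiblock weight vectors
#' across folds).  The pair maximizing mean validation correlation wins, ties
#' broken by higher stability, then by heavier regularization (`cx + cy`).
#' The winning pair is refitted on the full optimization set (deconfounded
#' with optimization-set betas) and evaluated on the outer test set.
#'
#' @param assembly a `block_assembly`.
#' @param confounds N x 4 confound matrix, row-aligned with the assembly.
#' @param plan a `split_plan`.
#' @param grid data frame of `(cx, cy)` pairs (see [default_grid()]).
#' @param prior_models optional list (one entry per outer split) of lists of
#'   previously extracted `rcca_model`s, applied as a deflation chain before
#'   fitting; used by [extract_dimensions()].
#' @param dimension_index 1-based index of the dimension being searched.
#' @return object of class `selection_result`: `best_cx`, `best_cy` (from the
#'   outer split with the highest test correlation), `best_split`,
#'   `test_canonical_correlations` (one per outer split), `stability_score`,
#'   `grid_table`, and `per_outer` (per split: selected pair, fitted
#'   `rcca_model`, confound models, outer-test `latent_dimension_report`).
#' @export
grid_search <- function(assembly, confounds, plan, grid, prior_models = NULL,
                        dimension_index = 1L) {
  stopifnot(inherits(assembly, "block_assembly"), inherits(plan, "split_plan"))
  grid <- normalize_grid(grid)
  X <- assembly$X; Y <- assembly$Y
  confounds <- as_num_matrix(confounds, "confounds")
  n_outer <- plan$n_outer
  prior_models <- prior_models %||% rep(list(list()), n_outer)

  per_outer <- vector("list", n_outer)
  grid_accum <- matrix(0, nrow(grid), 2L)  # mean val cc, stability sums

  for (o in seq_len(n_outer)) {
    chain <- prior_models[[o]]
    inner <- plan$inner[[o]]
    val_cc <- matrix(NA_real_, nrow(grid), length(inner))
    v_store <- vector("list", nrow(grid))
    for (i in seq_along(inner)) {
      tr <- inner[[i]]$training; va <- inner[[i]]$validation
      dec <- deconfound_partitions(X, Y, confounds, tr, list(val = va))
      dtr <- deflate_chain(dec$X_train, dec$Y_train, chain)
      dva <- deflate_chain(dec$X_val, dec$Y_val, chain)
      cache <- try(rcca_fold_cache(dtr$X, dtr$Y, dva$X, dva$Y), silent = TRUE)
      if (inherits(cache, "try-error")) next
      for (g in seq_len(nrow(grid))) {
        fit <- try(rcca_pair_cached(cache, grid$cx[g], grid$cy[g]), silent = TRUE)
        if (inherits(fit, "try-error")) next
        val_cc[g, i] <- cor(drop(cache$Xv %*% fit$u), drop(cache$Yv %*% fit$v))
        v_store[[g]] <- c(v_store[[g]], list(fit$v))
      }
    }
    mean_cc <- rowMeans(val_cc, na.rm = TRUE)
    stab <- vapply(v_store, weight_stability, numeric(1L))
    ok <- is.finite(mean_cc)
    if (!any(ok))
      stop_mb("outer split %d: all hyperparameter pairs degenerate", o,
              class = "mbrcca_value_error")
    if (any(!ok))
      warning(sprintf("outer split %d: %d degenerate pair(s) excluded",
                      o, sum(!ok)))
    ord <- order(mean_cc, stab, grid$cx + grid$cy, decreasing = TRUE,
                 na.last = TRUE)
    best <- ord[1L]

    opt <- plan$outer[[o]]$optimization; te <- plan$outer[[o]]$test
    dec <- deconfound_partitions(X, Y, confounds, opt, list(test = te))
    dop <- deflate_chain(dec$X_train, dec$Y_train, chain)
    dte <- deflate_chain(dec$X_test, dec$Y_test, chain)
    model <- fit_rcca(dop$X, dop$Y, grid$cx[best], grid$cy[best],
                      seed_cols = assembly$seed_cols,
                      dimension_index = dimension_index)
    report <- rcca_transform(model, dte$X, dte$Y)
    per_outer[[o]] <- list(
      best_cx = grid$cx[best], best_cy = grid$cy[best],
      stability = stab[best], mean_validation_cc = mean_cc[best],
      model = model, confound_model_x = dec$model_x,
      confound_model_y = dec$model_y,
      test_report = report,
      test_canonical_correlation = report$canonical_correlation)
    grid_accum <- grid_accum + cbind(ifelse(is.finite(mean_cc), mean_cc, 0),
                                     ifelse(is.finite(stab), stab, 0))
  }

  test_cc <- vapply(per_outer, `[[`, numeric(1L), "test_canonical_correlation")
  best_split <- which.max(test_cc)
  structure(list(
    best_cx = per_outer[[best_split]]$best_cx,
    best_cy = per_outer[[best_split]]$best_cy,
    best_split = best_split,
    test_canonical_correlations = test_cc,
    stability_score = mean(vapply(per_outer, `[[`, numeric(1L), "stability"),
                           na.rm = TRUE),
    grid_table = data.frame(grid, mean_validation_cc = grid_accum[, 1L] / n_outer,
                            stability = grid_accum[, 2L] / n_outer),
    per_outer = per_outer,
    dimension_index = as.integer(dimension_index)
  ), class = "selection_result")
}

## mean pairwise Pearson correlation of sign-aligned weight vectors
weight_stability <- function(vs) {
  vs <- Filter(Negate(is.null), vs)
  if (length(vs) < 2L) return(NA_real_)
  ref <- vs[[1L]]
  vs <- lapply(vs, function(v) v * sign(sum(v * ref) + .Machine$double.eps))
  cors <- c()
  for (i in seq_along(vs)[-length(vs)])
    for (j in (i + 1L):length(vs))
      cors <- c(cors, cor(vs[[i]], vs[[j]]))
  mean(cors)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection (dimension %d): best (cx, cy) = (%.3g, %.3g) from outer split %d\n",
              x$dimension_index, x$best_cx, x$best_cy, x$best_split))
  cat("  outer test canonical correlations:",
      sprintf("%.3f", x$test_canonical_correlations), "\n")
  invisible(x)
}

#' Sequentially extract latent dimensions
#'
#' Repeats hyperparameter search, per-outer-split permutation significance
#' testing, and projection deflation until `max_dims` dimensions have been
#' extracted or a dimension fails to reach significance in every outer split
#' (Bonferroni-corrected threshold `alpha / n_outer`).  Deflation is applied
#' per outer split with that split's own fitted models, so no information
#' crosses split boundaries.
#'
#' @inheritParams grid_search
#' @param max_dims maximum number of dimensions to extract.
#' @param n_perm permutations per significance test (default 1000); `0` skips
#'   significance testing and extracts `max_dims` dimensions unconditionally.
#' @param alpha significance level before Bonferroni correction over outer
#'   splits (default 0.05).
#' @param rng_seed integer seed for the permutation draws.
#' @return object of class `dimension_extraction`: `dimensions` (list of
#'   `selection_result`s, each with a `permutation` element holding one
#'   `permutation_result` per outer split), `n_extracted`, and
#'   `stopped_dimension` (the first non-significant selection, if any).
#' @export
extract_dimensions <- function(assembly, confounds, plan, grid, max_dims,
                               n_perm = 1000L, alpha = 0.05, rng_seed = 1L) {
  if (max_dims < 1L)
    stop_mb("max_dims must be >= 1", class = "mbrcca_value_error")
  n_outer <- plan$n_outer
  prior <- rep(list(list()), n_outer)
  dims <- list()
  stopped <- NULL
  for (d in seq_len(max_dims)) {
    sel <- grid_search(assembly, confounds, plan, grid,
                       prior_models = prior, dimension_index = d)
    if (n_perm > 0L) {
      sel$permutation <- lapply(seq_len(n_outer), function(o) {
        po <- sel$per_outer[[o]]
        permutation_test_discovery(
          assembly$X, assembly$Y, confounds, plan$family_id,
          optimization_idx = plan$outer[[o]]$optimization,
          test_idx = plan$outer[[o]]$test,
          cx = po$best_cx, cy = po$best_cy,
          prior_models = prior[[o]], seed_cols = assembly$seed_cols,
          n_perm = n_perm, rng_seed = derive_seed(rng_seed, 97L * d + o),
          alpha = alpha, n_comparisons = n_outer)
      })
      pvals <- vapply(sel$permutation, `[[`, numeric(1L), "p_value")
      sel$significant_all_splits <- all(pvals < alpha / n_outer)
    } else {
      sel$significant_all_splits <- TRUE
    }
    if (!sel$significant_all_splits) { stopped <- sel; break }
    dims[[d]] <- sel
    for (o in seq_len(n_outer))
      prior[[o]] <- c(prior[[o]], list(sel$per_outer[[o]]$model))
  }
  structure(list(dimensions = dims, n_extracted = length(dims),
                 stopped_dimension = stopped),
            class = "dimension_extraction")
}

#' @export
print.dimension_extraction <- function(x, ...) {
  cat(sprintf("Extracted %d significant latent dimension(s)\n", x$n_extracted))
  for (d in seq_along(x$dimensions)) {
    s <- x$dimensions[[d]]
    cat(sprintf("  dim %d: (cx, cy) = (%.3g, %.3g), outer test cc = %s\n",
                d, s$best_cx, s$best_cy,
                paste(sprintf("%.3f", s$test_canonical_correlations),
                      collapse = " ")))
  }
  invisible(x)
}
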