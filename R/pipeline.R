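#' Pipeline configuration
#'
#' Bundles the analysis settings: 5 x 5 nested cross-validation, 1000
#' permutations, Bonferroni level 0.05, up to 4 latent dimensions, 200
#' subjects reserved for validation-cohort confound estimation.
#'
#' @param n_outer,n_inner nested cross-validation folds.
#' @param grid data frame of `(cx, cy)` pairs (see [default_grid()]).
#' @param n_perm permutations per significance test.
#' @param alpha significance level (Bonferroni-corrected over outer splits
#'   inside the discovery phase).
#' @param max_dims maximum latent dimensions to extract.
#' @param n_estimation validation-cohort subjects reserved for confound
#'   estimation ("validation dataset 1").
#' @param sign_flip_variables behavior columns negated so larger = better
#'   (reaction-time convention).
#' @param rng_seed integer master seed; every stage derives its own stream.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_outer = 5L, n_inner = 5L, grid = default_grid(),
                            n_perm = 1000L, alpha = 0.05, max_dims = 4L,
                            n_estimation = 200L,
                            sign_flip_variables = character(),
                            rng_seed = 1L) {
  for (v in c(n_outer = n_outer, n_inner = n_inner, max_dims = max_dims,
              n_estimation = n_estimation, n_perm = n_perm))
    if (v < 1L) stop_mb("all counts must be positive", class = "mbrcca_config_error")
  if (alpha <= 0 || alpha >= 1)
    stop_mb("alpha must lie in (0, 1)", class = "mbrcca_config_error")
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 grid = normalize_grid(grid), n_perm = as.integer(n_perm),
                 alpha = alpha, max_dims = as.integer(max_dims),
                 n_estimation = as.integer(n_estimation),
                 sign_flip_variables = sign_flip_variables,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Run the discovery phase on a cohort
#'
#' Full discovery pipeline: behavioral sign adjustment, block assembly,
#' family-respecting nested split plan, hyperparameter search, sequential
#' latent-dimension extraction with projection deflation, and per-outer-split
#' permutation significance with Bonferroni correction.
#'
#' @param cohort a `multiblock_cohort` (the discovery cohort).
#' @param config a [pipeline_config()].
#' @return object of class `discovery_result`: the `dimension_extraction`,
#'   the `split_plan`, the assembled blocks, the per-parcel mean grey-matter
#'   volume (`spatial_covariate`, used later for spatially adjusted loading
#'   comparisons), and the configuration.
#' @export
run_discovery <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "multiblock_cohort"),
            inherits(config, "pipeline_config"))
  message(sprintf("[discovery] cohort '%s': N = %d, %d families",
                  cohort$cohort_label, length(cohort$subject_ids),
                  length(unique(cohort$family_id))))
  cohort <- adjust_reaction_time_sign(cohort, config$sign_flip_variables)
  assembly <- assemble_blocks(cohort)
  message(sprintf("[discovery] blocks: X %d x %d, Y %d x %d",
                  nrow(assembly$X), ncol(assembly$X),
                  nrow(assembly$Y), ncol(assembly$Y)))
  plan <- build_split_plan(cohort$family_id, config$n_outer, config$n_inner,
                           rng_seed = derive_seed(config$rng_seed, 11L))
  extraction <- extract_dimensions(
    assembly, cohort$confounds, plan, config$grid,
    max_dims = config$max_dims, n_perm = config$n_perm,
    alpha = config$alpha, rng_seed = derive_seed(config$rng_seed, 13L))
  message(sprintf("[discovery] %d significant latent dimension(s)",
                  extraction$n_extracted))
  structure(list(extraction = extraction, plan = plan, assembly = assembly,
                 confounds = cohort$confounds,
                 spatial_covariate = colMeans(assembly$X),
                 cohort_label = cohort$cohort_label, config = config),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("Discovery result ('%s'):\n", x$cohort_label))
  print(x$extraction)
  invisible(x)
}

#' Run the out-of-cohort validation phase
#'
#' For every significant discovery dimension: splits the validation cohort
#' into a confound-estimation subset ("dataset 1") and an evaluation subset
#' ("dataset 2"), deconfounds the evaluation subset with estimation-subset
#' betas and standardizes it with estimation-subset residual statistics,
#' projects it onto the discovery weights of the best outer split (deflation
#' chain included), runs the validation permutation test, and compares
#' loadings across cohorts (Pearson for the multiblock side; partial
#' correlation adjusted for the discovery cohort's per-parcel mean
#' grey-matter volume for the brain side).
#'
#' @param discovery a `discovery_result`.
#' @param cohort_val the validation `multiblock_cohort`.
#' @param config a [pipeline_config()]; defaults to the discovery config.
#' @return object of class `validation_result`: one `validation_report` per
#'   dimension (`validation_canonical_correlation`, validation loadings,
#'   loading similarities, `permutation`), plus the split indices.
#' @export
run_validation <- function(discovery, cohort_val, config = discovery$config) {
  stopifnot(inherits(discovery, "discovery_result"),
            inherits(cohort_val, "multiblock_cohort"))
  cohort_val <- adjust_reaction_time_sign(cohort_val, config$sign_flip_variables)
  assembly_val <- assemble_blocks(cohort_val)
  check_same_variables(discovery$assembly, assembly_val)
  message(sprintf("[validation] cohort '%s': N = %d",
                  cohort_val$cohort_label, length(cohort_val$subject_ids)))

  vs <- split_validation_for_deconfounding(
    cohort_val, config$n_estimation,
    rng_seed = derive_seed(config$rng_seed, 17L))
  est <- assemble_blocks(vs$estimation); ev <- assemble_blocks(vs$evaluation)
  cmx <- fit_confound_model(est$X, vs$estimation$confounds)
  cmy <- fit_confound_model(est$Y, vs$estimation$confounds)
  est_rx <- apply_confound_model(cmx, est$X, vs$estimation$confounds)
  est_ry <- apply_confound_model(cmy, est$Y, vs$estimation$confounds)
  ev_rx <- apply_confound_model(cmx, ev$X, vs$evaluation$confounds)
  ev_ry <- apply_confound_model(cmy, ev$Y, vs$evaluation$confounds)
  Xv <- standardize_cols(ev_rx, col_stats(est_rx))
  Yv <- standardize_cols(ev_ry, col_stats(est_ry))
  message(sprintf("[validation] estimation subset n = %d, evaluation subset n = %d",
                  nrow(est_rx), nrow(ev_rx)))

  dims <- discovery$extraction$dimensions
  reports <- lapply(seq_along(dims), function(d) {
    sel <- dims[[d]]
    o <- sel$best_split
    chain <- lapply(seq_len(d), function(k)
      discovery$extraction$dimensions[[k]]$per_outer[[o]]$model)
    proj <- project_cohort(chain, Xv, Yv, standardize = FALSE)

    ## discovery optimization-set matrices in the space the dimension was fit
    opt <- discovery$plan$outer[[o]]$optimization
    dec <- deconfound_partitions(discovery$assembly$X, discovery$assembly$Y,
                                 discovery$confounds, opt)
    dop <- deflate_chain(dec$X_train, dec$Y_train, chain[-length(chain)])
    vchain <- if (d > 1L) deflate_chain(Xv, Yv, chain[-length(chain)],
                                        standardize = FALSE)
              else list(X = Xv, Y = Yv)
    perm <- permutation_test_validation(
      dop$X, dop$Y, discovery$plan$family_id[opt],
      cx = sel$per_outer[[o]]$best_cx, cy = sel$per_outer[[o]]$best_cy,
      X_val = vchain$X, Y_val = vchain$Y,
      family_id_val = vs$evaluation$family_id,
      seed_cols = discovery$assembly$seed_cols,
      n_perm = config$n_perm,
      rng_seed = derive_seed(config$rng_seed, 23L + d),
      alpha = config$alpha)

    disc_report <- sel$per_outer[[o]]$test_report
    mb_sim <- compare_multiblock_loadings(disc_report$multiblock_loadings,
                                          proj$multiblock_loadings)
    br_sim <- compare_brain_loadings(disc_report$brain_loadings,
                                     proj$brain_loadings,
                                     discovery$spatial_covariate,
                                     n_perm = config$n_perm,
                                     rng_seed = derive_seed(config$rng_seed, 41L + d))
    structure(list(
      dimension_index = d,
      discovery_canonical_correlation = disc_report$canonical_correlation,
      validation_canonical_correlation = proj$canonical_correlation,
      validation_brain_loadings = proj$brain_loadings,
      validation_multiblock_loadings = proj$multiblock_loadings,
      loading_similarity_multiblock = mb_sim,
      loading_similarity_brain = br_sim[c("partial_r", "p")],
      permutation = perm
    ), class = "validation_report")
  })
  structure(list(reports = reports, estimation_idx = vs$estimation_idx,
                 evaluation_idx = vs$evaluation_idx,
                 cohort_label = cohort_val$cohort_label, config = config),
            class = "validation_result")
}

check_same_variables <- function(a, b) {
  bad <- c(setdiff(a$column_names_x, b$column_names_x),
           setdiff(b$column_names_x, a$column_names_x),
           setdiff(a$column_names_y, b$column_names_y),
           setdiff(b$column_names_y, a$column_names_y))
  if (length(bad))
    stop_mb("cohorts do not share the same variables; discrepant: %s",
            paste(unique(bad), collapse = ", "),
            class = "mbrcca_contract_error")
  if (!identical(a$column_names_x, b$column_names_x) ||
      !identical(a$column_names_y, b$column_names_y))
    stop_mb("cohorts share variables but in different column order",
            class = "mbrcca_contract_error")
  invisible(TRUE)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation of dimension %d: cc %.3f (discovery %.3f), perm p = %.4g\n",
    x$dimension_index, x$validation_canonical_correlation,
    x$discovery_canonical_correlation, x$permutation$p_value))
  cat(sprintf("  loading similarity: multiblock r = %.3f (p = %.3g), brain partial r = %.3f (p = %.3g)\n",
              x$loading_similarity_multiblock$r, x$loading_similarity_multiblock$p,
              x$loading_similarity_brain$partial_r, x$loading_similarity_brain$p))
  invisible(x)
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Validation result ('%s'): %d dimension(s)\n",
              x$cohort_label, length(x$reports)))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Swap-replication analysis
#'
#' Runs the full discovery + validation pipeline in both directions
#' (cohort A discovering, B validating; then roles reversed), verifying first
#' that the two cohorts share identical variable sets.
#'
#' @param cohort_a,cohort_b two `multiblock_cohort`s with identical variables.
#' @param config a [pipeline_config()].
#' @return object of class `swap_replication` with elements `a_to_b` and
#'   `b_to_a`, each a list of `discovery` and `validation` results.
#' @export
run_swap_replication <- function(cohort_a, cohort_b,
                                 config = pipeline_config()) {
  check_same_variables(assemble_blocks(cohort_a), assemble_blocks(cohort_b))
  disc_a <- run_discovery(cohort_a, config)
  val_ab <- if (disc_a$extraction$n_extracted > 0L)
    run_validation(disc_a, cohort_b, config) else NULL
  disc_b <- run_discovery(cohort_b, config)
  val_ba <- if (disc_b$extraction$n_extracted > 0L)
    run_validation(disc_b, cohort_a, config) else NULL
  structure(list(a_to_b = list(discovery = disc_a, validation = val_ab),
                 b_to_a = list(discovery = disc_b, validation = val_ba)),
            class = "swap_replication")
}

#' @export
print.swap_replication <- function(x, ...) {
  cat("Swap replication\n== direction A -> B ==\n")
  print(x$a_to_b$discovery)
  if (!is.null(x$a_to_b$validation)) print(x$a_to_b$validation)
  cat("== direction B -> A ==\n")
  print(x$b_to_a$discovery)
  if (!is.null(x$b_to_a$validation)) print(x$b_to_a$validation)
  invisible(x)
}
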