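#' Specify a synthetic multiblock cohort with planted latent structure
#'
#' Defines the population model from which [generate_cohort()] draws: a linear
#' Gaussian factor model in which `n_latent` latent factors are shared between
#' the brain block and the multiblock side (seeds + behaviors), with
#' per-dimension target canonical correlations, isotropic Gaussian variable
#' noise, confound contamination, and an additive family-level random effect
#' on the latent factors.
#'
#' Target correlations are planted in closed form: with variable noise
#' standard deviation `sigma`, the block-level factor scores attenuate the
#' shared factor by `alpha_k = rho_k * (1 + sigma^2)` so that the population
#' canonical correlation of dimension `k` equals `rho_k` exactly (requires
#' `rho_k * (1 + sigma^2) <= 1`).
#'
#' When loading matrices are not supplied, unit-norm mutually orthogonal
#' columns are drawn from the QR decomposition of a seeded Gaussian matrix.
#'
#' @param n_subjects number of subjects.
#' @param n_parcels,n_seeds,n_behaviors block widths (defaults 232 / 6 / 32,
#'   matching a Schaefer-200 + Melbourne-32 parcellation, the tripartite
#'   hippocampal parcellation per hemisphere, and the shared behavioral set).
#' @param n_latent number of planted latent dimensions.
#' @param latent_strengths strictly decreasing target canonical correlations
#'   in `(0, 1]`, one per dimension.
#' @param brain_loadings optional `n_parcels x n_latent` matrix, unit-norm
#'   orthogonal columns.
#' @param multiblock_loadings optional `(n_seeds + n_behaviors) x n_latent`
#'   matrix, unit-norm orthogonal columns.
#' @param confound_strength fraction of each variable's variance contributed
#'   by the four confounds (age, age-squared, gender, TIV); `0` disables
#'   contamination.  Alternatively pass an explicit `confound_effects` matrix
#'   (4 x total variables) of coefficients on standardized confounds.
#' @param confound_effects see `confound_strength`.
#' @param noise_sd standard deviation of iid Gaussian variable noise.
#' @param family_sizes positive integers summing to `n_subjects`; default all
#'   singletons.
#' @param family_effect variance of the family-level random effect relative to
#'   the subject-level latent variance (default 0.3).
#' @param rng_seed integer seed; the whole cohort is deterministic in it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects, n_parcels = 232L, n_seeds = 6L,
                           n_behaviors = 32L, n_latent,
                           latent_strengths,
                           brain_loadings = NULL, multiblock_loadings = NULL,
                           confound_strength = 0, confound_effects = NULL,
                           noise_sd = 1, family_sizes = NULL,
                           family_effect = 0.3, rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop_mb("n_subjects must be a positive count", class = "mbrcca_spec_error")
  n_latent <- as.integer(n_latent)
  n_y <- n_seeds + n_behaviors
  if (n_latent < 1L || n_latent > min(n_parcels, n_y))
    stop_mb("n_latent must be in 1..min(n_parcels, n_seeds + n_behaviors)",
            class = "mbrcca_spec_error")
  if (length(latent_strengths) != n_latent)
    stop_mb("latent_strengths must have one entry per latent dimension",
            class = "mbrcca_spec_error")
  if (any(latent_strengths <= 0) || any(latent_strengths > 1))
    stop_mb("latent_strengths must lie in (0, 1]", class = "mbrcca_value_error")
  if (n_latent > 1L && any(diff(latent_strengths) >= 0))
    stop_mb("latent_strengths must be strictly decreasing",
            class = "mbrcca_spec_error")
  if (noise_sd < 0)
    stop_mb("noise_sd must be nonnegative", class = "mbrcca_value_error")
  family_sizes <- as.integer(family_sizes %||% rep(1L, n_subjects))
  if (any(family_sizes < 1L) || sum(family_sizes) != n_subjects)
    stop_mb("family_sizes must be positive counts summing to n_subjects",
            class = "mbrcca_spec_error")

  set.seed(rng_seed)
  if (is.null(brain_loadings))
    brain_loadings <- orthonormal_columns(n_parcels, n_latent)
  if (is.null(multiblock_loadings))
    multiblock_loadings <- orthonormal_columns(n_y, n_latent)
  check_orthonormal(brain_loadings, n_parcels, n_latent, "brain_loadings")
  check_orthonormal(multiblock_loadings, n_y, n_latent, "multiblock_loadings")

  if (is.null(confound_effects)) {
    ## coefficient matrix on standardized confounds, scaled per variable so
    ## confounds contribute ~confound_strength of total variance
    confound_effects <- matrix(0, 4L, n_parcels + n_y)
    if (confound_strength > 0) {
      if (confound_strength >= 1)
        stop_mb("confound_strength must be in [0, 1)", class = "mbrcca_value_error")
      signal_var <- c(rowSums(brain_loadings^2), rowSums(multiblock_loadings^2)) +
        noise_sd^2
      G <- matrix(rnorm(4L * (n_parcels + n_y)), 4L)
      G <- sweep(G, 2L, sqrt(colSums(G^2)), "/")
      confound_effects <- sweep(
        G, 2L, sqrt(confound_strength / (1 - confound_strength) * signal_var), "*")
    }
  }
  if (!identical(dim(confound_effects), c(4L, as.integer(n_parcels + n_y))))
    stop_mb("confound_effects must be 4 x (n_parcels + n_seeds + n_behaviors)",
            class = "mbrcca_spec_error")

  structure(list(
    n_subjects = n_subjects, n_parcels = as.integer(n_parcels),
    n_seeds = as.integer(n_seeds), n_behaviors = as.integer(n_behaviors),
    n_latent = n_latent, latent_strengths = as.numeric(latent_strengths),
    brain_loadings = brain_loadings, multiblock_loadings = multiblock_loadings,
    confound_effects = confound_effects, noise_sd = noise_sd,
    family_sizes = family_sizes, family_effect = family_effect,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_spec")
}

orthonormal_columns <- function(nr, nc) {
  qr.Q(qr(matrix(rnorm(nr * nc), nr, nc)))[, seq_len(nc), drop = FALSE]
}

check_orthonormal <- function(M, nr, nc, what) {
  if (!is.matrix(M) || nrow(M) != nr || ncol(M) != nc)
    stop_mb("%s must be %d x %d", what, nr, nc, class = "mbrcca_spec_error")
  G <- crossprod(M)
  if (max(abs(G - diag(nc))) > 1e-8)
    stop_mb("%s columns must be unit-norm and mutually orthogonal", what,
            class = "mbrcca_spec_error")
  invisible(M)
}

#' Generate a synthetic multiblock cohort
#'
#' Draws one cohort from the population model of a [synthetic_spec()]:
#' subject-level latent factors (plus a family-level random effect shared
#' within families), block-level factor scores attenuated to hit the target
#' canonical correlations, loading expansion into the brain and seed+behavior
#' blocks, additive confound contamination on standardized confounds, and iid
#' Gaussian variable noise.  Confounds follow cohort templates: age uniform on
#' `age_range`, gender Bernoulli(0.5), TIV Gaussian.
#'
#' @param spec a `synthetic_spec`.
#' @param cohort_label free-text label stored on the cohort.
#' @param age_range age sampling range in years; `c(22, 37)` emulates a young
#'   adult cohort, `c(36, 100)` an aging cohort.
#' @return object of class `multiblock_cohort` with elements `subject_ids`,
#'   `brain` (N x P), `seeds` (N x S), `behavior` (N x B), `confounds`
#'   (N x 4: `age`, `age_sq`, `gender`, `tiv`), `family_id`, `cohort_label`.
#' @export
generate_cohort <- function(spec, cohort_label = "synthetic",
                            age_range = c(22, 37)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ## a child seed keeps the data stream independent of the loading draws
  ## made by the constructor under the raw seed
  set.seed(derive_seed(spec$rng_seed, 1L))

  n <- spec$n_subjects; K <- spec$n_latent
  P <- spec$n_parcels; S <- spec$n_seeds; B <- spec$n_behaviors
  sigma <- spec$noise_sd
  alpha <- spec$latent_strengths * (1 + sigma^2)
  if (any(alpha > 1 + 1e-12))
    stop_mb(paste("noise_sd too large for the target canonical correlations:",
                  "need latent_strengths * (1 + noise_sd^2) <= 1"),
            class = "mbrcca_value_error")
  alpha <- pmin(alpha, 1)

  n_fam <- length(spec$family_sizes)
  family_id <- rep(sprintf("F%04d", seq_len(n_fam)), spec$family_sizes)

  ## shared latent factors: subject effect + family effect, unit total variance
  w <- spec$family_effect
  e  <- matrix(rnorm(n * K), n, K)
  fa <- matrix(rnorm(n_fam * K), n_fam, K)[rep(seq_len(n_fam), spec$family_sizes), , drop = FALSE]
  z <- (e + sqrt(w) * fa) / sqrt(1 + w)

  ## block-level factor scores, attenuated so canonical correlation = rho_k
  Zx <- sweep(z, 2L, sqrt(alpha), "*") +
    sweep(matrix(rnorm(n * K), n, K), 2L, sqrt(1 - alpha), "*")
  Zy <- sweep(z, 2L, sqrt(alpha), "*") +
    sweep(matrix(rnorm(n * K), n, K), 2L, sqrt(1 - alpha), "*")

  X  <- Zx %*% t(spec$brain_loadings)      + sigma * matrix(rnorm(n * P), n)
  YM <- Zy %*% t(spec$multiblock_loadings) + sigma * matrix(rnorm(n * (S + B)), n)

  age <- runif(n, age_range[1L], age_range[2L])
  conf <- cbind(age = age, age_sq = age^2,
                gender = rbinom(n, 1L, 0.5), tiv = rnorm(n, 1500, 150))
  if (any(spec$confound_effects != 0)) {
    Cs <- scale(conf)
    X  <- X  + Cs %*% spec$confound_effects[, seq_len(P), drop = FALSE]
    YM <- YM + Cs %*% spec$confound_effects[, P + seq_len(S + B), drop = FALSE]
  }

  colnames(X) <- sprintf("parcel_%03d", seq_len(P))
  seed_names <- if (S == 6L)
    c("lh_head", "rh_head", "lh_post_ca", "rh_post_ca",
      "lh_post_sub", "rh_post_sub")
  else sprintf("seed_%02d", seq_len(S))
  YM <- YM + 0.5  # shift toward positive volume-like values; irrelevant after centering
  seeds <- YM[, seq_len(S), drop = FALSE]
  behavior <- YM[, S + seq_len(B), drop = FALSE] - 0.5
  colnames(seeds) <- seed_names
  if (B > 0) colnames(behavior) <- sprintf("beh_%02d", seq_len(B))

  cohort <- new_multiblock_cohort(
    subject_ids = sprintf("%s_S%04d", toupper(substr(cohort_label, 1, 3)), seq_len(n)),
    brain = X + 0.6, seeds = seeds, behavior = behavior,
    confounds = conf, family_id = family_id, cohort_label = cohort_label)
  attr(cohort, "synthetic_spec") <- spec
  cohort
}

new_multiblock_cohort <- function(subject_ids, brain, seeds, behavior,
                                  confounds, family_id, cohort_label) {
  n <- length(subject_ids)
  for (blk in list(brain, seeds, behavior, confounds))
    if (nrow(blk) != n)
      stop_mb("all blocks must share row count", class = "mbrcca_contract_error")
  if (anyNA(brain) || anyNA(seeds) || anyNA(behavior) || anyNA(confounds))
    stop_mb("cohort blocks must be free of missing values",
            class = "mbrcca_value_error")
  if (max(abs(confounds[, "age_sq"] - confounds[, "age"]^2)) > 1e-8)
    stop_mb("age_sq must equal age squared", class = "mbrcca_contract_error")
  rownames(brain) <- rownames(seeds) <- rownames(behavior) <-
    rownames(confounds) <- subject_ids
  structure(list(subject_ids = subject_ids, brain = brain, seeds = seeds,
                 behavior = behavior, confounds = confounds,
                 family_id = family_id, cohort_label = cohort_label),
            class = "multiblock_cohort")
}

#' Draw an independent cohort from the same population model
#'
#' New subjects, fresh noise and families, but the same loadings and latent
#' strengths -- emulating a second, independent cohort for out-of-cohort
#' validation.  With `scramble_loadings = TRUE` the rows of both loading
#' matrices are permuted, producing a negative-control cohort whose latent
#' structure no longer matches the discovery cohort's.
#'
#' @param spec the `synthetic_spec` used for the discovery cohort.
#' @param n_subjects size of the twin cohort.
#' @param rng_seed seed for the twin draw (and the scramble, if any).
#' @param family_sizes family layout; default all singletons (an
#'   unrelated-subjects cohort).
#' @param scramble_loadings permute loading rows to break shared structure.
#' @param cohort_label,age_range passed to [generate_cohort()].
#' @return a `multiblock_cohort`.
#' @export
make_twin_cohort <- function(spec, n_subjects, rng_seed,
                             family_sizes = NULL, scramble_loadings = FALSE,
                             cohort_label = "twin", age_range = c(36, 100)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  twin <- spec
  twin$n_subjects <- as.integer(n_subjects)
  if (is.na(twin$n_subjects) || twin$n_subjects < 1L)
    stop_mb("n_subjects must be a positive count", class = "mbrcca_spec_error")
  twin$family_sizes <- as.integer(family_sizes %||% rep(1L, n_subjects))
  if (sum(twin$family_sizes) != twin$n_subjects)
    stop_mb("family_sizes must sum to n_subjects", class = "mbrcca_spec_error")
  twin$rng_seed <- as.integer(rng_seed)
  if (scramble_loadings) {
    set.seed(derive_seed(rng_seed, 9L))
    twin$brain_loadings <- twin$brain_loadings[sample(nrow(twin$brain_loadings)), , drop = FALSE]
    twin$multiblock_loadings <- twin$multiblock_loadings[sample(nrow(twin$multiblock_loadings)), , drop = FALSE]
  }
  generate_cohort(twin, cohort_label = cohort_label, age_range = age_range)
}

#' Write / read a cohort as tab-separated block tables
#'
#' One TSV per block (`brain.tsv`, `seeds.tsv`, `behavior.tsv`) plus
#' `covariates.tsv` holding the four confounds and the family label; every
#' file has `subject_id` as its first column and a header row.  Numeric values
#' are written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param cohort a `multiblock_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @seealso [load_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multiblock_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(mat, file, extra = NULL) {
    df <- data.frame(subject_id = cohort$subject_ids, check.names = FALSE)
    for (j in colnames(mat)) df[[j]] <- sprintf("%.17g", mat[, j])
    if (!is.null(extra)) df <- cbind(df, extra)
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(cohort$brain, "brain.tsv")
  wr(cohort$seeds, "seeds.tsv")
  wr(cohort$behavior, "behavior.tsv")
  wr(cohort$confounds, "covariates.tsv",
     extra = data.frame(family_id = cohort$family_id))
  spec <- attr(cohort, "synthetic_spec")
  if (!is.null(spec)) write_synthetic_spec(spec, file.path(dir, "spec.json"))
  invisible(dir)
}

#' Serialize / restore a synthetic cohort specification as JSON
#'
#' Written automatically as a `spec.json` sidecar by [write_cohort()] for
#' generated cohorts; the round trip preserves every numeric value exactly.
#'
#' @param spec a `synthetic_spec`.
#' @param path file path.
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_subjects", "n_parcels", "n_seeds", "n_behaviors", "n_latent",
              "rng_seed"))
    s[[f]] <- as.integer(s[[f]])
  s$family_sizes <- as.integer(s$family_sizes)
  for (f in c("brain_loadings", "multiblock_loadings", "confound_effects"))
    s[[f]] <- as.matrix(s[[f]])
  structure(s, class = "synthetic_spec")
}

#' @export
print.multiblock_cohort <- function(x, ...) {
  cat(sprintf("Multiblock cohort '%s': N = %d (%d families)\n",
              x$cohort_label, length(x$subject_ids), length(unique(x$family_id))))
  cat(sprintf("  brain %d parcels | seeds %d | behavior %d | confounds %s\n",
              ncol(x$brain), ncol(x$seeds), ncol(x$behavior),
              paste(colnames(x$confounds), collapse = ", ")))
  invisible(x)
}

#' Subset a cohort by row index
#'
#' @param cohort a `multiblock_cohort`.
#' @param idx integer or logical row index.
#' @return the subsetted `multiblock_cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  new_multiblock_cohort(cohort$subject_ids[idx],
                        cohort$brain[idx, , drop = FALSE],
                        cohort$seeds[idx, , drop = FALSE],
                        cohort$behavior[idx, , drop = FALSE],
                        cohort$confounds[idx, , drop = FALSE],
                        cohort$family_id[idx], cohort$cohort_label)
}
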