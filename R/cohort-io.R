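#' Load a multiblock cohort from tab-separated block tables
#'
#' Reads the brain, seed, behavior and covariate tables written by
#' [write_cohort()] (or any files with the same layout: `subject_id` first
#' column, header row, tab-separated), verifies that all files describe the
#' same subject set, aligns rows to the brain table's order, and drops (with a
#' message reporting the count) any subject carrying a missing value in any
#' used column -- the analysis operates on variables free of missing values.
#'
#' @param paths named list or vector with entries `brain`, `seeds`,
#'   `behavior`, `covariates`; or a single directory containing
#'   `brain.tsv`, `seeds.tsv`, `behavior.tsv`, `covariates.tsv`.
#' @param schema named list: `confound_columns` (default `age`, `age_sq`,
#'   `gender`, `tiv`), `family_column` (default `family_id`; if the column is
#'   absent every subject becomes their own family).
#' @param cohort_label label stored on the cohort.
#' @return a `multiblock_cohort`.
#' @export
load_cohort <- function(paths, schema = list(), cohort_label = "cohort") {
  if (length(paths) == 1L && is.character(paths) && dir.exists(paths)) {
    nm <- c("brain", "seeds", "behavior", "covariates")
    paths <- setNames(file.path(paths, paste0(nm, ".tsv")), nm)
  }
  paths <- as.list(paths)
  need <- c("brain", "seeds", "behavior", "covariates")
  if (!all(need %in% names(paths)))
    stop_mb("paths must name files for: %s", paste(need, collapse = ", "),
            class = "mbrcca_config_error")
  confound_columns <- schema$confound_columns %||% c("age", "age_sq", "gender", "tiv")
  family_column <- schema$family_column %||% "family_id"

  tabs <- lapply(paths[need], function(p)
    read.delim(p, colClasses = "character", check.names = FALSE))
  ids <- lapply(tabs, function(t) t$subject_id)
  ref <- ids$brain
  for (nm in need) {
    missing_ids <- setdiff(ref, ids[[nm]])
    extra_ids <- setdiff(ids[[nm]], ref)
    if (length(missing_ids) || length(extra_ids))
      stop_mb("subject_id mismatch in '%s' table: missing [%s], unexpected [%s]",
              nm, paste(head(missing_ids, 5L), collapse = ", "),
              paste(head(extra_ids, 5L), collapse = ", "),
              class = "mbrcca_alignment_error")
    tabs[[nm]] <- tabs[[nm]][match(ref, ids[[nm]]), , drop = FALSE]
  }

  numify <- function(tab, cols, file) {
    m <- matrix(NA_real_, nrow(tab), length(cols), dimnames = list(NULL, cols))
    for (j in cols) {
      raw <- tab[[j]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("", "NA")))
      if (length(bad))
        stop_mb("non-numeric value '%s' at row %d, column '%s' of %s",
                raw[bad[1L]], bad[1L], j, file, class = "mbrcca_parse_error")
      m[, j] <- val
    }
    m
  }
  val_cols <- function(tab, drop) setdiff(colnames(tab), c("subject_id", drop))
  brain <- numify(tabs$brain, val_cols(tabs$brain, NULL), "brain")
  seeds <- numify(tabs$seeds, val_cols(tabs$seeds, NULL), "seeds")
  behavior <- numify(tabs$behavior, val_cols(tabs$behavior, NULL), "behavior")
  if (!all(confound_columns %in% colnames(tabs$covariates)))
    stop_mb("covariates table lacks confound column(s): %s",
            paste(setdiff(confound_columns, colnames(tabs$covariates)), collapse = ", "),
            class = "mbrcca_config_error")
  confounds <- numify(tabs$covariates, confound_columns, "covariates")
  colnames(confounds) <- c("age", "age_sq", "gender", "tiv")
  family_id <- if (family_column %in% colnames(tabs$covariates))
    tabs$covariates[[family_column]] else ref

  keep <- !(rowSums(is.na(brain)) + rowSums(is.na(seeds)) +
              rowSums(is.na(behavior)) + rowSums(is.na(confounds)) > 0)
  if (any(!keep))
    message(sprintf("load_cohort: dropped %d subject(s) with missing values: %s",
                    sum(!keep), paste(ref[!keep], collapse = ", ")))

  new_multiblock_cohort(ref[keep], brain[keep, , drop = FALSE],
                        seeds[keep, , drop = FALSE],
                        behavior[keep, , drop = FALSE],
                        confounds[keep, , drop = FALSE],
                        family_id[keep], cohort_label)
}

#' Flip the sign of reaction-time-like behavioral variables
#'
#' Negates the listed behavior columns so that larger values uniformly mean
#' better performance (reaction times are faster when smaller); applying the
#' adjustment twice restores the original values.
#'
#' @param cohort a `multiblock_cohort`.
#' @param variable_names behavior column names to negate (may be empty).
#' @return the adjusted `multiblock_cohort`.
#' @export
adjust_reaction_time_sign <- function(cohort, variable_names) {
  stopifnot(inherits(cohort, "multiblock_cohort"))
  unknown <- setdiff(variable_names, colnames(cohort$behavior))
  if (length(unknown))
    stop_mb("unknown behavioral variable(s): %s", paste(unknown, collapse = ", "),
            class = "mbrcca_config_error")
  cohort$behavior[, variable_names] <- -cohort$behavior[, variable_names]
  cohort
}

#' Assemble the brain-multiblock design matrices
#'
#' Builds `X` (brain parcels; hippocampus-related parcels must already be
#' absent -- any overlap with the seed names is an error, mirroring the
#' nullification of hippocampus-related parcels in the brain set) and
#' `Y = [seeds | behaviors]` in that order.
#'
#' @param cohort a `multiblock_cohort`.
#' @param seed_names names of the seed columns (default: all seed-block
#'   columns of the cohort).
#' @param domain_tag optional per-behavior grouping label (e.g. alertness /
#'   cognition / emotion), recycled notation kept as given.
#' @return object of class `block_assembly`: matrices `X` and `Y`,
#'   `column_names_x`, `column_names_y`, `block_membership` (`"seed"` or
#'   `"behavior"` per Y column), `seed_cols` (indices into Y), `domain_tag`,
#'   `subject_ids`.
#' @export
assemble_blocks <- function(cohort, seed_names = colnames(cohort$seeds),
                            domain_tag = NULL) {
  stopifnot(inherits(cohort, "multiblock_cohort"))
  if (!setequal(seed_names, colnames(cohort$seeds)))
    stop_mb("seed_names must match the cohort's seed columns",
            class = "mbrcca_config_error")
  overlap <- intersect(colnames(cohort$brain), seed_names)
  if (length(overlap))
    stop_mb("hippocampus-related parcel(s) present in the brain block: %s",
            paste(overlap, collapse = ", "), class = "mbrcca_assembly_error")
  S <- ncol(cohort$seeds); B <- ncol(cohort$behavior)
  Y <- cbind(cohort$seeds[, seed_names, drop = FALSE], cohort$behavior)
  structure(list(
    X = cohort$brain, Y = Y,
    column_names_x = colnames(cohort$brain), column_names_y = colnames(Y),
    block_membership = c(rep("seed", S), rep("behavior", B)),
    seed_cols = seq_len(S),
    domain_tag = domain_tag,
    subject_ids = cohort$subject_ids
  ), class = "block_assembly")
}

#' @export
print.block_assembly <- function(x, ...) {
  cat(sprintf("Block assembly: X %d x %d, Y %d x %d (%d seeds + %d behaviors)\n",
              nrow(x$X), ncol(x$X), nrow(x$Y), ncol(x$Y),
              sum(x$block_membership == "seed"),
              sum(x$block_membership == "behavior")))
  invisible(x)
}
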