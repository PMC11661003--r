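# Shared study parameters for the analysis workflow.  Sourced by the
# numbered drivers; everything downstream is deterministic in MASTER_SEED.

library(mbrcca)

MASTER_SEED <- 20260922L

RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohorts")

# Synthetic stand-ins shaped like the two cohorts of interest: a young
# cohort of 1047 subjects with twin/sibling families and an aging cohort of
# 601 unrelated subjects; 232 brain parcels, 6 hippocampal seed volumes
# (tripartite parcellation x hemisphere), 32 shared behavioral variables.
# Two planted latent dimensions with canonical correlations 0.7 and 0.4,
# isotropic variable noise, 20% confound variance.
study_spec <- function() {
  synthetic_spec(
    n_subjects = 1047, n_parcels = 232, n_seeds = 6, n_behaviors = 32,
    n_latent = 2, latent_strengths = c(0.7, 0.4), noise_sd = 0.5,
    confound_strength = 0.2,
    family_sizes = rep(c(1L, 2L, 4L), c(349L, 175L, 87L)),
    rng_seed = MASTER_SEED)
}

study_config <- function() {
  pipeline_config(
    n_outer = 5, n_inner = 5,
    grid = expand.grid(cx = c(0.1, 0.5, 0.9), cy = c(0.1, 0.5, 0.9)),
    n_perm = 199, alpha = 0.05, max_dims = 3, n_estimation = 200,
    rng_seed = MASTER_SEED + 1L)
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
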