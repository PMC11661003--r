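#!/usr/bin/env Rscript
# Out-of-cohort validation: project the aging cohort onto the discovery
# weights (deconfounded via the 200-subject estimation split), test each
# dimension by permutation, and compare loadings across cohorts.

source("analysis/00_parameters.R")

discovery <- readRDS(file.path(RESULTS_DIR, "discovery", "discovery.rds"))
aging <- load_cohort(file.path(COHORT_DIR, "aging"), cohort_label = "aging_validation")

validation <- run_validation(discovery, aging, study_config())
print(validation)

val_table <- do.call(rbind, lapply(validation$reports, function(r)
  data.frame(dimension = r$dimension_index,
             discovery_cc = r$discovery_canonical_correlation,
             validation_cc = r$validation_canonical_correlation,
             perm_p = r$permutation$p_value,
             multiblock_loading_r = r$loading_similarity_multiblock$r,
             multiblock_loading_p = r$loading_similarity_multiblock$p,
             brain_loading_partial_r = r$loading_similarity_brain$partial_r,
             brain_loading_p = r$loading_similarity_brain$p)))
write_tsv(val_table, file.path(RESULTS_DIR, "validation", "validation.tsv"))

for (r in validation$reports) {
  write_tsv(data.frame(variable = discovery$assembly$column_names_y,
                       loading = r$validation_multiblock_loadings),
            file.path(RESULTS_DIR, "validation",
                      sprintf("multiblock_loadings_dim%d.tsv", r$dimension_index)))
  write_tsv(data.frame(null_cc = r$permutation$null_values),
            file.path(RESULTS_DIR, "validation",
                      sprintf("permutation_null_dim%d.tsv", r$dimension_index)))
}
message("Validation artifacts written under ", file.path(RESULTS_DIR, "validation"))
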