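#!/usr/bin/env Rscript
# Discovery phase on the young cohort: nested 5x5 family-respecting
# cross-validation, regularization search, sequential latent-dimension
# extraction with projection deflation, per-outer-split permutation
# significance (Bonferroni over the 5 splits).

source("analysis/00_parameters.R")

young <- load_cohort(file.path(COHORT_DIR, "young"), cohort_label = "young_discovery")
config <- study_config()

discovery <- run_discovery(young, config)
print(discovery)

dims <- discovery$extraction$dimensions
sel_table <- do.call(rbind, lapply(seq_along(dims), function(d) {
  s <- dims[[d]]
  data.frame(dimension = d, outer_split = seq_along(s$per_outer),
             cx = vapply(s$per_outer, `[[`, numeric(1), "best_cx"),
             cy = vapply(s$per_outer, `[[`, numeric(1), "best_cy"),
             test_cc = s$test_canonical_correlations,
             perm_p = vapply(s$permutation, `[[`, numeric(1), "p_value"),
             best = seq_along(s$per_outer) == s$best_split)
}))
write_tsv(sel_table, file.path(RESULTS_DIR, "discovery", "selection.tsv"))

for (d in seq_along(dims)) {
  s <- dims[[d]]
  rep_ <- s$per_outer[[s$best_split]]$test_report
  write_tsv(data.frame(variable = discovery$assembly$column_names_x,
                       loading = rep_$brain_loadings),
            file.path(RESULTS_DIR, "discovery",
                      sprintf("brain_loadings_dim%d.tsv", d)))
  write_tsv(data.frame(variable = discovery$assembly$column_names_y,
                       block = discovery$assembly$block_membership,
                       loading = rep_$multiblock_loadings),
            file.path(RESULTS_DIR, "discovery",
                      sprintf("multiblock_loadings_dim%d.tsv", d)))
  write_rcca_model(s$per_outer[[s$best_split]]$model,
                   file.path(RESULTS_DIR, "discovery",
                             sprintf("model_dim%d.json", d)))
}

# full state handed to the validation / swap drivers
saveRDS(discovery, file.path(RESULTS_DIR, "discovery", "discovery.rds"))
message("Discovery artifacts written under ", file.path(RESULTS_DIR, "discovery"))
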