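#!/usr/bin/env Rscript
# Simulate the two synthetic cohorts (young discovery cohort with families,
# aging validation cohort of unrelated subjects) and write them out as
# tab-separated block tables.

source("analysis/00_parameters.R")

spec <- study_spec()
young <- generate_cohort(spec, "young_discovery", age_range = c(22, 37))
aging <- make_twin_cohort(spec, 601, rng_seed = MASTER_SEED + 2L,
                          cohort_label = "aging_validation",
                          age_range = c(36, 100))

write_cohort(young, file.path(COHORT_DIR, "young"))
write_cohort(aging, file.path(COHORT_DIR, "aging"))

print(young)
print(aging)
message("Planted canonical correlations: ",
        paste(spec$latent_strengths, collapse = ", "))
message("Cohorts written under ", COHORT_DIR)
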