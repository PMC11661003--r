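Package: mbrcca
Title: Multiblock Regularized Canonical Correlation Analysis with
    Discovery-Validation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a whole-brain grey-matter block to a concatenated block of
    hippocampal-subregion volumes and behavioral variables via regularized
    canonical correlation analysis (RCCA). Provides leakage-free deconfounding
    of age, age-squared, gender and total intracranial volume, nested
    cross-validation with family-aware splitting for hyperparameter selection,
    projection deflation for sequential latent-dimension extraction,
    family-structure-respecting permutation inference with Bonferroni
    correction over outer splits, and out-of-cohort validation by projecting an
    independent cohort onto discovery weights. A synthetic multiblock cohort
    generator with planted latent structure, confound contamination and family
    clustering supports end-to-end testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
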