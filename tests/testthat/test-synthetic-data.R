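test_that("generation is deterministic under the spec seed", {
  spec <- test_spec(n = 60, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c_ <- generate_cohort(test_spec(n = 60, seed = 43))
  expect_false(identical(a$brain, c_$brain))
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(test_spec(n = 0), class = "mbrcca_spec_error")
  expect_error(synthetic_spec(10, 5, 2, 2, n_latent = 2,
                              latent_strengths = c(0.4, 0.7), noise_sd = 0.1),
               class = "mbrcca_spec_error")  # not decreasing
  expect_error(synthetic_spec(10, 5, 2, 2, n_latent = 1,
                              latent_strengths = 1.2, noise_sd = 0.1),
               class = "mbrcca_value_error")
  expect_error(synthetic_spec(10, 5, 2, 2, n_latent = 1,
                              latent_strengths = 0.5, noise_sd = -1),
               class = "mbrcca_value_error")
  expect_error(synthetic_spec(10, 5, 2, 2, n_latent = 1,
                              latent_strengths = 0.5, noise_sd = 0.1,
                              family_sizes = c(3, 3)),
               class = "mbrcca_spec_error")
  # a target of 0.9 is unreachable once variable noise eats the shared signal
  expect_error(generate_cohort(synthetic_spec(
    50, 5, 2, 2, n_latent = 1, latent_strengths = 0.9, noise_sd = 1)),
    class = "mbrcca_value_error")
})

test_that("a noiseless shared factor yields canonical correlation 1", {
  spec <- synthetic_spec(200, 10, 3, 4, n_latent = 1, latent_strengths = 1,
                         noise_sd = 0, confound_strength = 0, rng_seed = 1)
  coh <- generate_cohort(spec)
  m <- fit_rcca(coh$brain, cbind(coh$seeds, coh$behavior), 0, 0)
  expect_equal(m$train_canonical_correlation, 1, tolerance = 1e-8)
})

test_that("planted canonical correlations are recovered by a classical CCA oracle", {
  spec <- synthetic_spec(2000, 12, 4, 4, n_latent = 2,
                         latent_strengths = c(0.7, 0.4), noise_sd = 0.5,
                         confound_strength = 0, rng_seed = 3)
  coh <- generate_cohort(spec)
  rho <- oracle_cca(coh$brain, cbind(coh$seeds, coh$behavior))$rho
  expect_equal(rho[1], 0.7, tolerance = 0.05 / 0.7)
  expect_equal(rho[2], 0.4, tolerance = 0.05 / 0.4)
})

test_that("family members share latent signal; singletons do not", {
  fam_score_cor <- function(family_sizes, seed) {
    spec <- synthetic_spec(400, 10, 3, 4, n_latent = 1, latent_strengths = 0.8,
                           noise_sd = 0.3, family_sizes = family_sizes,
                           rng_seed = seed)
    coh <- generate_cohort(spec)
    s <- drop(scale(coh$brain) %*% spec$brain_loadings[, 1])
    idx <- matrix(seq_len(400), nrow = 2)  # sibling pairs live in adjacent rows
    cor(s[idx[1, ]], s[idx[2, ]])
  }
  expect_gt(fam_score_cor(rep(2L, 200), seed = 7), 0.1)
  # all-singleton layout: "adjacent pairs" are unrelated subjects
  expect_lt(abs(fam_score_cor(rep(1L, 400), seed = 7)), 0.15)
})

test_that("noise compensation holds the planted correlation across feasible noise levels", {
  # the closed-form conversion trades variable noise against latent
  # attenuation, so the population canonical correlation stays at the target
  # until the feasibility bound latent_strengths * (1 + noise_sd^2) <= 1
  cc_at <- function(noise) {
    spec <- synthetic_spec(1500, 12, 4, 4, n_latent = 1, latent_strengths = 0.5,
                           noise_sd = noise, confound_strength = 0, rng_seed = 11)
    coh <- generate_cohort(spec)
    fit_rcca(coh$brain, cbind(coh$seeds, coh$behavior), 0.5, 0.5)$train_canonical_correlation
  }
  ccs <- vapply(c(0, 0.4, 0.9), cc_at, numeric(1))
  expect_true(all(abs(ccs - 0.5) < 0.06))
})

test_that("cohort TSV round trip is bit-exact", {
  coh <- generate_cohort(test_spec(n = 12, seed = 5,
                                   family_sizes = rep(c(1L, 2L), c(4L, 4L))))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- load_cohort(dir, cohort_label = coh$cohort_label)
  expect_identical(back$subject_ids, coh$subject_ids)
  expect_identical(back$family_id, coh$family_id)
  for (blk in c("brain", "seeds", "behavior", "confounds"))
    expect_identical(unname(back[[blk]]), unname(coh[[blk]]))
})

test_that("the spec sidecar round-trips exactly and regenerates the same cohort", {
  spec <- test_spec(n = 15, P = 7, S = 3, B = 4, confound_strength = 0.2,
                    seed = 6, family_sizes = rep(c(1L, 2L), c(5L, 5L)))
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "spec.json")))
  back <- read_synthetic_spec(file.path(dir, "spec.json"))
  expect_equal(back, spec, tolerance = 0)
  expect_identical(generate_cohort(back)$brain, coh$brain)
})

test_that("twin cohorts share the planted structure; scrambled twins do not", {
  spec <- test_spec(n = 800, P = 20, S = 4, B = 8, strengths = c(0.7, 0.4),
                    noise_sd = 0.5, seed = 21)
  disc <- generate_cohort(spec)
  m <- fit_rcca(disc$brain, cbind(disc$seeds, disc$behavior), 0.5, 0.5)
  proj_cc <- function(coh)
    rcca_transform(m, coh$brain, cbind(coh$seeds, coh$behavior))$canonical_correlation
  twin <- make_twin_cohort(spec, 800, rng_seed = 31)
  scram <- make_twin_cohort(spec, 800, rng_seed = 31, scramble_loadings = TRUE)
  expect_equal(proj_cc(twin), 0.7, tolerance = 0.1 / 0.7)
  expect_lt(abs(proj_cc(scram)), 0.15)
  expect_error(make_twin_cohort(spec, 0, rng_seed = 1),
               class = "mbrcca_spec_error")
})
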