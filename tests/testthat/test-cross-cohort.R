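test_that("projecting the discovery data reproduces the discovery report", {
  coh <- generate_cohort(test_spec(n = 150, P = 10, S = 3, B = 5, seed = 50))
  db <- deconfounded_blocks(coh)
  m <- fit_rcca(db$X, db$Y, 0.5, 0.5, seed_cols = db$assembly$seed_cols)
  direct <- rcca_transform(m, db$X, db$Y)
  proj <- project_cohort(m, db$X, db$Y)
  expect_identical(proj$canonical_correlation, direct$canonical_correlation)
  expect_identical(proj$brain_loadings, direct$brain_loadings)
  # renamed columns break the projection contract
  Xbad <- db$X; colnames(Xbad)[2] <- "imposter"
  err <- expect_error(project_cohort(m, Xbad, db$Y),
                      class = "mbrcca_contract_error")
  expect_match(conditionMessage(err), "imposter")
})

test_that("twin-cohort projection recovers the planted effect size", {
  spec <- test_spec(n = 800, P = 20, S = 4, B = 8, strengths = 0.6,
                    noise_sd = 0.5, seed = 51)
  disc <- generate_cohort(spec)
  twin <- make_twin_cohort(spec, 800, rng_seed = 52)
  db <- deconfounded_blocks(disc)
  tb <- deconfounded_blocks(twin)
  m <- fit_rcca(db$X, db$Y, 0.5, 0.5)
  proj <- project_cohort(m, tb$X, tb$Y)
  expect_equal(proj$canonical_correlation, 0.6, tolerance = 0.1 / 0.6)
})

test_that("multiblock loading similarity matches the direct Pearson formula", {
  set.seed(53)
  a <- rnorm(38); b <- 0.6 * a + rnorm(38)
  out <- compare_multiblock_loadings(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(out$r, r_direct, tolerance = 1e-12)
  expect_equal(compare_multiblock_loadings(a, a)$r, 1, tolerance = 1e-12)
  expect_equal(compare_multiblock_loadings(a, -a)$r, -1, tolerance = 1e-12)
  expect_error(compare_multiblock_loadings(a, rep(1, 38)),
               class = "mbrcca_value_error")
  expect_error(compare_multiblock_loadings(a, b[1:10]),
               class = "mbrcca_contract_error")
})

test_that("spatially adjusted brain similarity equals the residualization oracle", {
  set.seed(54)
  cov_ <- rnorm(232)
  a <- 0.5 * cov_ + rnorm(232)
  b <- 0.4 * cov_ + 0.5 * a + rnorm(232)
  out <- compare_brain_loadings(a, b, cov_, n_perm = 99, rng_seed = 1)
  oracle <- cor(residuals(lm(a ~ cov_)), residuals(lm(b ~ cov_)))
  expect_equal(out$partial_r, oracle, tolerance = 1e-12)
  # covariate orthogonal to both: partial r collapses to the plain r
  qa <- residuals(lm(a ~ cov_)); qb <- residuals(lm(b ~ cov_))
  out2 <- compare_brain_loadings(qa, qb, cov_, n_perm = 9, rng_seed = 1)
  expect_equal(out2$partial_r, cor(qa, qb), tolerance = 1e-10)
  # degenerate: both maps equal to the covariate
  expect_error(compare_brain_loadings(cov_, cov_, cov_, n_perm = 9),
               class = "mbrcca_value_error")
})

test_that("validation effect sizes do not exceed discovery training effect sizes on average", {
  gaps <- vapply(1:20, function(s) {
    spec <- test_spec(n = 150, P = 12, S = 3, B = 5, strengths = 0.6,
                      noise_sd = 0.6, seed = 100 + s)
    disc <- generate_cohort(spec)
    twin <- make_twin_cohort(spec, 150, rng_seed = 200 + s)
    db <- deconfounded_blocks(disc)
    tb <- deconfounded_blocks(twin)
    m <- fit_rcca(db$X, db$Y, 0.5, 0.5)
    m$train_canonical_correlation -
      project_cohort(m, tb$X, tb$Y)$canonical_correlation
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("loading similarity separates true twins from scrambled twins", {
  spec <- test_spec(n = 600, P = 20, S = 4, B = 8, strengths = 0.6,
                    noise_sd = 0.5, seed = 55)
  disc <- generate_cohort(spec)
  db <- deconfounded_blocks(disc)
  m <- fit_rcca(db$X, db$Y, 0.5, 0.5)
  disc_rep <- rcca_transform(m, db$X, db$Y)
  sim_to <- function(coh) {
    cb <- deconfounded_blocks(coh)
    proj <- rcca_transform(m, cb$X, cb$Y)
    compare_multiblock_loadings(disc_rep$multiblock_loadings,
                                proj$multiblock_loadings)$r
  }
  r_twin <- sim_to(make_twin_cohort(spec, 600, rng_seed = 56))
  r_scram <- sim_to(make_twin_cohort(spec, 600, rng_seed = 56,
                                     scramble_loadings = TRUE))
  expect_gt(r_twin, 0.9)
  # scrambling destroys the latent match; the residual similarity that
  # remains (loadings of a fixed projection inherit a component proportional
  # to the weight vector) must stay clearly below the true-twin similarity
  expect_lt(r_scram, r_twin - 0.1)
})

test_that("swap replication runs both directions and rejects mismatched cohorts", {
  spec <- test_spec(n = 400, P = 15, S = 4, B = 6, strengths = c(0.8, 0.5),
                    noise_sd = 0.5, seed = 57)
  a <- generate_cohort(spec, "cohort_a")
  b <- make_twin_cohort(spec, 400, rng_seed = 58, cohort_label = "cohort_b")
  cfg <- pipeline_config(n_outer = 3, n_inner = 3,
                         grid = data.frame(cx = 0.8, cy = 0.8),
                         n_perm = 199, max_dims = 2, n_estimation = 60,
                         rng_seed = 59)
  suppressMessages(swap <- run_swap_replication(a, b, cfg))
  n_ab <- swap$a_to_b$discovery$extraction$n_extracted
  n_ba <- swap$b_to_a$discovery$extraction$n_extracted
  expect_gte(n_ab, 1L)
  expect_identical(n_ab, n_ba)
  expect_lte(swap$a_to_b$validation$reports[[1]]$permutation$p_value, 0.05)
  expect_lte(swap$b_to_a$validation$reports[[1]]$permutation$p_value, 0.05)

  # disjoint variable sets must fail before any fitting
  small <- generate_cohort(test_spec(n = 400, P = 10, S = 4, B = 6, seed = 60))
  expect_error(run_swap_replication(a, small, cfg),
               class = "mbrcca_contract_error")
})
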