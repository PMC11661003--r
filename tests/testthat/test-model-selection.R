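test_that("singleton families split into balanced, disjoint, covering folds", {
  plan <- build_split_plan(sprintf("s%03d", 1:100), 5, 5, rng_seed = 1)
  test_sizes <- vapply(plan$outer, function(o) length(o$test), 1L)
  expect_identical(test_sizes, rep(20L, 5))
  all_test <- sort(unlist(lapply(plan$outer, `[[`, "test")))
  expect_identical(all_test, 1:100)
  for (o in seq_len(5)) {
    expect_length(intersect(plan$outer[[o]]$optimization,
                            plan$outer[[o]]$test), 0L)
    for (i in seq_len(5)) {
      inner <- plan$inner[[o]][[i]]
      expect_length(intersect(inner$training, inner$validation), 0L)
      expect_setequal(c(inner$training, inner$validation),
                      plan$outer[[o]]$optimization)
    }
  }
})

test_that("families never straddle any split", {
  fam <- rep(sprintf("f%02d", 1:30), times = rep(c(1L, 2L, 4L), 10))
  plan <- build_split_plan(fam, 5, 3, rng_seed = 2)
  sides_ok <- function(ids, other) {
    # every family in play sits wholly on one side
    pool <- c(ids, other)
    groups <- split(seq_along(fam), fam)
    groups <- groups[vapply(groups, function(g) any(g %in% pool), logical(1))]
    all(vapply(groups, function(g)
      all(g %in% ids) || all(g %in% other), logical(1)))
  }
  for (o in seq_len(5)) {
    expect_true(sides_ok(plan$outer[[o]]$test, plan$outer[[o]]$optimization))
    for (i in seq_len(3))
      expect_true(sides_ok(plan$inner[[o]][[i]]$validation,
                           plan$inner[[o]][[i]]$training))
  }
})

test_that("split plans are deterministic and demand enough families", {
  fam <- rep(sprintf("f%02d", 1:20), each = 3)
  expect_identical(build_split_plan(fam, 5, 5, rng_seed = 7),
                   build_split_plan(fam, 5, 5, rng_seed = 7))
  expect_error(build_split_plan(rep("one_family", 10), 5, 5),
               class = "mbrcca_value_error")
})

test_that("a single-pair grid is selected as-is", {
  coh <- generate_cohort(test_spec(n = 120, P = 8, S = 3, B = 4, seed = 30))
  asm <- assemble_blocks(coh)
  plan <- build_split_plan(coh$family_id, 3, 3, rng_seed = 1)
  sel <- grid_search(asm, coh$confounds, plan, data.frame(cx = 0.6, cy = 0.4))
  expect_equal(sel$best_cx, 0.6)
  expect_equal(sel$best_cy, 0.4)
  expect_length(sel$test_canonical_correlations, 3L)
  expect_true(all(abs(sel$test_canonical_correlations) <= 1))
})

test_that("pure CCA loses the grid search when n < P (validation correlation collapses)", {
  spec <- synthetic_spec(80, 100, 4, 6, n_latent = 1, latent_strengths = 0.6,
                         noise_sd = 0.5, rng_seed = 31)
  coh <- generate_cohort(spec)
  asm <- assemble_blocks(coh)
  plan <- build_split_plan(coh$family_id, 3, 3, rng_seed = 2)
  sel <- grid_search(asm, coh$confounds, plan, expand.grid(cx = c(0, 1), cy = c(0, 1)))
  expect_true(sel$best_cx > 0 || sel$best_cy > 0)
})

test_that("extraction respects the max_dims bound", {
  coh <- generate_cohort(test_spec(n = 150, P = 10, S = 3, B = 5, seed = 32))
  asm <- assemble_blocks(coh)
  plan <- build_split_plan(coh$family_id, 3, 3, rng_seed = 3)
  ext <- extract_dimensions(asm, coh$confounds, plan,
                            data.frame(cx = 0.5, cy = 0.5),
                            max_dims = 1, n_perm = 0)
  expect_identical(ext$n_extracted, 1L)
  expect_error(extract_dimensions(asm, coh$confounds, plan,
                                  data.frame(cx = 0.5, cy = 0.5),
                                  max_dims = 0, n_perm = 0),
               class = "mbrcca_value_error")
})

test_that("a dominant global factor is absorbed first, exposing the secondary contrast", {
  P <- 20L; R <- 10L
  global_x <- rep(1, P) / sqrt(P)
  contrast_x <- rep(c(1, -1), P / 2) / sqrt(P)
  global_y <- rep(1, R) / sqrt(R)
  contrast_y <- rep(c(1, -1), R / 2) / sqrt(R)
  spec <- synthetic_spec(600, P, 4, R - 4, n_latent = 2,
                         latent_strengths = c(0.8, 0.5), noise_sd = 0.5,
                         brain_loadings = cbind(global_x, contrast_x),
                         multiblock_loadings = cbind(global_y, contrast_y),
                         rng_seed = 33)
  coh <- generate_cohort(spec)
  asm <- assemble_blocks(coh)
  plan <- build_split_plan(coh$family_id, 3, 3, rng_seed = 4)
  ext <- extract_dimensions(asm, coh$confounds, plan,
                            data.frame(cx = 0.5, cy = 0.5),
                            max_dims = 2, n_perm = 0)
  rep1 <- ext$dimensions[[1]]$per_outer[[ext$dimensions[[1]]$best_split]]$test_report
  rep2 <- ext$dimensions[[2]]$per_outer[[ext$dimensions[[2]]$best_split]]$test_report
  expect_gt(abs_cosine(rep1$brain_loadings, global_x), 0.8)
  expect_gt(abs_cosine(rep2$brain_loadings, contrast_x), 0.7)
})
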