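test_that("identical single-column blocks give canonical correlation 1", {
  x <- matrix(rnorm(30), dimnames = list(NULL, "a"))
  m <- fit_rcca(x, x, 0, 0)
  expect_equal(m$train_canonical_correlation, 1, tolerance = 1e-12)
})

test_that("cx = cy = 0 reproduces classical CCA (generalized-eigenproblem oracle)", {
  set.seed(20)
  X <- matrix(rnorm(50 * 3), 50); Y <- X[, 1:2] + matrix(rnorm(50 * 2), 50)
  m <- fit_rcca(X, Y, 0, 0)
  o <- oracle_cca(X, Y)
  expect_equal(m$train_canonical_correlation, o$rho[1], tolerance = 1e-8)
  expect_gte(abs_cosine(m$u, o$u1), 1 - 1e-8)
  expect_gte(abs_cosine(m$v, o$v1), 1 - 1e-8)
})

test_that("cx = cy = 1 reproduces the leading SVD pair of the cross-covariance", {
  set.seed(21)
  X <- matrix(rnorm(60 * 4), 60); Y <- matrix(rnorm(60 * 3), 60)
  Y[, 1] <- Y[, 1] + X[, 2]
  m <- fit_rcca(X, Y, 1, 1)
  o <- oracle_pls(X, Y)
  expect_gte(abs_cosine(m$u, o$u1), 1 - 1e-8)
  expect_gte(abs_cosine(m$v, o$v1), 1 - 1e-8)
})

test_that("the weight normalization honors the shrunken unit-variance constraint", {
  set.seed(22)
  X <- matrix(rnorm(80 * 5), 80); Y <- matrix(rnorm(80 * 4), 80)
  for (c_ in c(0, 0.5, 1)) {
    m <- fit_rcca(X, Y, c_, c_)
    Xs <- scale(X)
    Rx <- (1 - c_) * crossprod(Xs) / 79 + c_ * diag(5)
    expect_equal(drop(t(m$u) %*% Rx %*% m$u), 1, tolerance = 1e-8)
  }
})

test_that("the sign convention makes the dominant seed weight positive", {
  coh <- generate_cohort(test_spec(n = 100, P = 8, S = 3, B = 4, seed = 23))
  asm <- assemble_blocks(coh)
  m <- fit_rcca(asm$X, asm$Y, 0.5, 0.5, seed_cols = asm$seed_cols)
  j <- asm$seed_cols[which.max(abs(m$v[asm$seed_cols]))]
  expect_gt(m$v[j], 0)
  # the canonical correlation itself is invariant to a joint sign flip
  sx <- scale(asm$X) %*% m$u; sy <- scale(asm$Y) %*% m$v
  expect_equal(cor(-sx, -sy), cor(sx, sy))
})

test_that("transform is consistent on training data and matches a direct correlation oracle", {
  coh <- generate_cohort(test_spec(n = 150, P = 10, S = 3, B = 5, seed = 24))
  X <- coh$brain; Y <- cbind(coh$seeds, coh$behavior)
  m <- fit_rcca(X[1:100, ], Y[1:100, ], 0.5, 0.5)
  tr <- rcca_transform(m, X[1:100, ], Y[1:100, ])
  expect_equal(tr$canonical_correlation, m$train_canonical_correlation,
               tolerance = 1e-12)
  expect_equal(tr$canonical_correlation,
               cor(tr$brain_scores, tr$multiblock_scores), tolerance = 1e-12)
  # held-out loadings are plain per-variable Pearson correlations with scores
  te <- rcca_transform(m, X[101:150, ], Y[101:150, ])
  expect_equal(te$brain_loadings, drop(cor(X[101:150, ], te$brain_scores)),
               tolerance = 1e-12)
  expect_equal(te$multiblock_loadings,
               drop(cor(Y[101:150, ], te$multiblock_scores)), tolerance = 1e-12)
  expect_true(all(abs(te$brain_loadings) <= 1 + 1e-12))
  # single brain variable: perfect self-correlation
  m1 <- fit_rcca(X[, 1, drop = FALSE], Y, 0.5, 0.5)
  t1 <- rcca_transform(m1, X[, 1, drop = FALSE], Y)
  expect_equal(abs(unname(t1$brain_loadings)), 1, tolerance = 1e-12)
  # mismatched columns are a contract error
  expect_error(rcca_transform(m, X[, 1:5], Y), class = "mbrcca_contract_error")
})

test_that("projection deflation removes its own score direction and yields orthogonal dimensions", {
  coh <- generate_cohort(test_spec(n = 200, P = 12, S = 4, B = 6,
                                   strengths = c(0.8, 0.5), seed = 25))
  X <- coh$brain; Y <- cbind(coh$seeds, coh$behavior)
  m1 <- fit_rcca(X, Y, 0.3, 0.3)
  d <- rcca_deflate(X, Y, m1)
  s1 <- scale(X, m1$x_center, m1$x_scale) %*% m1$u
  expect_lt(max(abs(crossprod(s1, d$X %*% m1$u))), 1e-10)
  m2 <- fit_rcca(d$X, d$Y, 0.3, 0.3, dimension_index = 2)
  t1 <- rcca_transform(m1, X, Y)
  t2 <- rcca_transform(m2, d$X, d$Y)
  expect_lt(abs(cor(t1$brain_scores, t2$brain_scores)), 1e-8)
  expect_lt(abs(cor(t1$multiblock_scores, t2$multiblock_scores)), 1e-8)
  # an all-zero weight vector cannot define a dimension
  broken <- m1; broken$u[] <- 0
  expect_error(rcca_deflate(X, Y, broken), class = "mbrcca_degenerate_error")
})

test_that("regularization orders training correlations when n < P (overfit ordering)", {
  set.seed(26)
  X <- matrix(rnorm(30 * 50), 30); Y <- matrix(rnorm(30 * 10), 30)
  cc0 <- fit_rcca(X, Y, 0, 0)$train_canonical_correlation
  cc1 <- fit_rcca(X, Y, 1, 1)$train_canonical_correlation
  expect_gte(cc0, cc1)
})

test_that("invalid inputs are rejected", {
  X <- matrix(rnorm(20), 10); Y <- matrix(rnorm(20), 10)
  expect_error(fit_rcca(X, Y, -0.1, 0), class = "mbrcca_value_error")
  expect_error(fit_rcca(X, Y, 0, 1.5), class = "mbrcca_value_error")
  X[1] <- NA
  expect_error(fit_rcca(X, Y, 0, 0), class = "mbrcca_value_error")
})

test_that("a model survives a JSON round trip and projects identically", {
  coh <- generate_cohort(test_spec(n = 80, P = 6, S = 2, B = 3, seed = 27))
  X <- coh$brain; Y <- cbind(coh$seeds, coh$behavior)
  m <- fit_rcca(X, Y, 0.7, 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_rcca_model(m, path)
  m2 <- read_rcca_model(path)
  expect_equal(m2$u, m$u)
  expect_equal(rcca_transform(m2, X, Y)$canonical_correlation,
               rcca_transform(m, X, Y)$canonical_correlation)
})
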