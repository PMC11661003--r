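# Independent oracles used to check the RCCA implementation.  These are
# deliberately brute-force: direct matrix construction of the classical-CCA
# generalized eigenproblem and a plain SVD of the cross-covariance for the
# PLS limit.

oracle_cca <- function(X, Y) {
  Xs <- scale(X); Ys <- scale(Y); n <- nrow(Xs)
  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  e <- eigen(M)
  rho <- sqrt(pmax(Re(e$values), 0))
  ord <- order(rho, decreasing = TRUE)
  u1 <- Re(e$vectors[, ord[1L]])
  v1 <- drop(solve(Syy, t(Sxy)) %*% u1)
  list(rho = rho[ord], u1 = u1 / sqrt(sum(u1^2)), v1 = v1 / sqrt(sum(v1^2)))
}

oracle_pls <- function(X, Y) {
  Xs <- scale(X); Ys <- scale(Y); n <- nrow(Xs)
  sv <- svd(crossprod(Xs, Ys) / (n - 1), nu = 1L, nv = 1L)
  list(u1 = drop(sv$u), v1 = drop(sv$v), d1 = sv$d[1L])
}

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# standard two-block test fixture: planted two-dimensional latent structure
test_spec <- function(n = 400L, P = 20L, S = 4L, B = 8L,
                      strengths = c(0.7, 0.4), noise_sd = 0.5,
                      confound_strength = 0, family_sizes = NULL, seed = 1L) {
  synthetic_spec(n_subjects = n, n_parcels = P, n_seeds = S, n_behaviors = B,
                 n_latent = length(strengths), latent_strengths = strengths,
                 noise_sd = noise_sd, confound_strength = confound_strength,
                 family_sizes = family_sizes, rng_seed = seed)
}

deconfounded_blocks <- function(cohort) {
  asm <- assemble_blocks(cohort)
  cmx <- fit_confound_model(asm$X, cohort$confounds)
  cmy <- fit_confound_model(asm$Y, cohort$confounds)
  list(X = apply_confound_model(cmx, asm$X, cohort$confounds),
       Y = apply_confound_model(cmy, asm$Y, cohort$confounds),
       assembly = asm)
}
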