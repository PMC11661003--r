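---
title: "Multiblock regularized CCA: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock regularized CCA: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbrcca)
```

## The scientific problem

Structural covariance analyses ask how inter-individual variation in
regional grey-matter volume co-varies across the brain and with behavior.
`mbrcca` implements a brain–multiblock design for this question: a brain
block $X$ ($N \times P$ parcelwise grey-matter volumes, hippocampus-related
parcels excluded) is linked to a multiblock matrix
$Y = [\,\text{seeds} \mid \text{behaviors}\,]$ ($N \times R$) concatenating
hippocampal-subregion volumes (the "seed" block: the tripartite
anterior-head / posterior-CA / posterior-subiculum parcellation, per
hemisphere, hence six seed variables by default) with a set of behavioral
variables shared across cohorts.  Canonical correlation analysis finds
weights $u, v$ maximizing $\mathrm{corr}(Xu, Yv)$; the per-subject
projections $Xu$ (brain score) and $Yv$ (multiblock score) define a latent
dimension, and their Pearson correlation is the effect size reported
throughout.  Loadings — the correlation of each original variable with its
own block's score — are what gets interpreted, not the raw weights.

## The estimator

With $P$ in the hundreds, classical CCA overfits badly.  The estimator is a
regularized CCA with convex covariance shrinkage:

$$R_x = (1 - c_x)\,\Sigma_{xx} + c_x I, \qquad
  R_y = (1 - c_y)\,\Sigma_{yy} + c_y I, \qquad c_x, c_y \in [0, 1],$$

maximizing $u^\top \Sigma_{xy} v$ subject to $u^\top R_x u = v^\top R_y v = 1$.
The solution is the leading singular pair of
$K = R_x^{-1/2}\, \Sigma_{xy}\, R_y^{-1/2}$ mapped back through the
whitening.  This parametrization interpolates two well-defined limits that
double as independent test oracles: $c = 0$ is classical CCA (a generalized
eigenproblem) and $c = 1$ is partial least squares (the leading SVD pair of
the cross-covariance).  Covariances use the $n - 1$ denominator; all
columns are z-scored with *training* statistics before fitting and the
statistics are stored in the model.  At $c_x = 0$ with $n \le P$ the
shrunken covariance is rank-deficient; its inverse square root is computed
on the retained eigenspace (relative eigenvalue floor $10^{-10}$), which
reproduces the degenerate classical-CCA behavior the grid search is meant
to penalize.

Two conventions remove indeterminacies:

* **Sign**: the largest-magnitude entry of $v$ among the seed columns is
  made positive, so weights are comparable across refits and cohorts.
* **Ties in model selection** go to the higher stability score, then to the
  larger $c_x + c_y$ (heavier regularization).

## Sequential dimensions by projection deflation

After a dimension is accepted, its variance is removed by projection
deflation of each block along its own score direction,
$X \leftarrow X - s_x (s_x^\top s_x)^{-1} s_x^\top X$ with $s_x = Xu$
(similarly for $Y$), which makes subsequent training scores exactly
orthogonal to the accepted ones.  Held-out and validation partitions are
deflated with the *training-fit* weights and the partition's own scores —
the leakage-free reading of "removing the dimension's variance".  Deflation
returns matrices in the deflating model's standardized space, and a model
fitted on deflated data records the statistics of that space, so chains of
deflations are self-consistent on new data.  Row permutation commutes with
projection deflation, which is what lets the permutation tests deflate once
and permute inside the loop.

## Deconfounding without leakage

Age, age², gender and total intracranial volume are regressed out of every
$X$ and $Y$ column by OLS with intercept.  Coefficients are estimated on
the training side of whatever split is active and applied unchanged to
held-out data: training residuals are exactly orthogonal to the centered
confounds ($<10^{-10}$), held-out residuals only approximately — that gap
is the price of avoiding train–test leakage, and the test suite asserts
both sides (exact orthogonality on training folds; a measurable difference
between train-only and full-data deconfounding once the age distribution
shifts).  Age and age² enter as two separate raw regressors (no centering
before squaring); gender is 0/1; confounds are not standardized before the
regression — with an intercept and full-rank confounds the residuals are
identical either way.

For cross-cohort validation the discovery-phase confound model cannot be
reused when the cohorts' age ranges differ, so the validation cohort is
split: `n_estimation` subjects (default 200, "validation dataset 1")
estimate the confound regressors and the column standardization; all
validation statistics are computed on the remainder ("validation dataset
2") only.

## Nested cross-validation and model selection

Hyperparameters are tuned by 5 outer × 5 inner nested cross-validation.
Splits never separate family members: families are packed into folds
greedily (largest first, seeded random tie-breaks), which balances fold
sizes well for HCP-like family-size distributions.  Within each outer
split, every $(c_x, c_y)$ pair on the grid is fitted on each inner training
fold (deconfounded with that fold's own betas) and scored on the inner
validation fold; pairs are ranked by mean validation correlation, with a
stability tie-break defined as the mean pairwise Pearson correlation of
sign-aligned $v$ vectors across the inner folds.  The winning pair is
refitted on the full optimization set and evaluated on the outer test set.
Tuning is done per outer split (standard nested CV); the alternative — one
global pair — would give a single model but leak the outer test sets into
selection.  The default grid is
$\{0, 0.25, 0.5, 0.75, 0.9, 0.99, 1\}^2$; the bundled analysis scripts use
a coarser $\{0.1, 0.5, 0.9\}^2$ grid, which is where selection lands on
data of this shape anyway.

Reported loadings come from the outer split with the highest test
canonical correlation ("best model"), while all five splits are stored.

## Permutation inference

Significance of a dimension is tested per outer split by shuffling the rows
of $Y$ to break the $X$–$Y$ association: the model is refitted on the
permuted optimization set with the selected hyperparameters and evaluated
on the permuted test set, 1000 iterations by default, one-sided
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$.  The
$+1$ convention avoids $p = 0$ and is conservative relative to a raw
percentage.  A dimension is accepted only if significant in **all** outer
splits at the Bonferroni-corrected level $\alpha/5$; extraction stops at
the first dimension that fails.  Note the granularity constraint this
implies: with $n_{\text{perm}}$ permutations the smallest attainable $p$ is
$1/(n_{\text{perm}} + 1)$, so at $\alpha = 0.05$ over 5 splits at least 199
permutations are required for *any* dimension to pass.

Shuffles respect family structure in exchangeability-block style: whole
families are exchanged only with families of identical size and members
are shuffled within families; for all-singleton cohorts this reduces to an
unrestricted permutation (verified uniform by enumeration at $N = 5$).
Optimization and test sets are permuted separately — families never
straddle a split, so each side is shuffled within itself.  In the
validation phase the $Y$ rows are permuted independently within the
discovery optimization set and within validation dataset 2 and both are
used in every iteration (the single-set alternative would leave the refit
model's weights unperturbed and test a strictly narrower null).
"As extreme or more extreme" is read one-sided ($\ge$), since canonical
correlations are reported as positive effect sizes.

## Cross-cohort validation and the swap replication

A discovery dimension generalizes if projecting the (deconfounded,
estimation-standardized) validation dataset 2 onto the discovery weights
yields a significant canonical correlation.  Validation data are
standardized with statistics from the estimation subset, matching the
confound logic (discovery statistics are the configurable alternative).
Loading similarity across cohorts uses a plain Pearson correlation for the
multiblock side and, for the brain side, a partial correlation adjusted for
a spatial covariate — by default the discovery cohort's per-parcel mean
grey-matter volume, exposed as an input so smoothness-matched surrogates
can be substituted.  Its significance comes from a permutation of parcel
labels (1000 by default, two-sided on $|r|$) rather than the analytic $t$,
to stay robust to residual spatial structure; a spin-type test on sphere
coordinates is out of reach at this abstraction level because no atlas
geometry is represented.  The swap replication reruns the whole pipeline
with cohort roles reversed.

## The synthetic cohort generator

Real HCP-style cohorts are access-restricted, so the package carries a
first-class generator whose ground truth defines the acceptance surface.
It is a linear Gaussian factor model: $K$ latent factors $z_k$ are shared
between blocks, each block sees an attenuated copy
$z^{(x)}_k = \sqrt{\alpha_k}\, z_k + \sqrt{1 - \alpha_k}\, \varepsilon_k$
(independently for $Y$), loadings expand factors into variables
(orthonormal loading columns, QR of a seeded Gaussian matrix when not
supplied), and iid Gaussian noise with standard deviation $\sigma$ is added
to every variable.  The attenuation is chosen in closed form,
$\alpha_k = \rho_k (1 + \sigma^2)$, so the *population* canonical
correlation of dimension $k$ equals the target $\rho_k$ exactly for every
feasible noise level ($\rho_k(1 + \sigma^2) \le 1$; infeasible
combinations are an error).  A consequence worth stating: varying
`noise_sd` inside the feasible region does **not** move the canonical
correlation — it is held at the target by construction — which the
property tests assert directly.

Families add a Gaussian random effect on the latent factors with variance
ratio 0.3 relative to the subject-level effect (configurable); any positive
sharing suffices to exercise the grouped splitting and permutation
machinery, and no within-family model is claimed beyond that.  Confounds
follow cohort templates (age uniform on a cohort-specific range, gender
Bernoulli(0.5), TIV Gaussian around 1500 ml) and contaminate all variables
through a coefficient matrix on standardized confounds scaled so that
confounds contribute a chosen fraction (`confound_strength`, 0.2 in the
bundled analyses) of each variable's variance.  All $Y$ columns are treated
identically — nothing distinguishes seed from behavior columns
statistically, since no evidence suggests they should be scaled
differently.

What the generator does *not* emulate: spatial autocorrelation between
parcels (noise is isotropic; parcels are abstract named columns),
non-Gaussian behavioral distributions, site effects, or any nonlinear
confound action.  Passing tests therefore demonstrate correctness of the
estimation and inference machinery under the stated model, not robustness
to those real-data features.  One concrete consequence shows up in the
negative controls: because loadings of a fixed projection inherit a
component proportional to the weight vector itself
($\mathrm{cor}(Y_j, Yv) \propto (\Sigma_{yy} v)_j$, and
$\Sigma_{yy} \approx \text{structure} + \sigma^2 I$), a loading-similarity
correlation between a discovery cohort and a loading-scrambled control
stays well above zero even though the latent structure is destroyed.  The
discriminative statistic for generalizability is the projected canonical
correlation and its permutation test, and that is what the scrambled-twin
tests assert; loading similarity is asserted only to drop clearly below
the matched-twin level.

## Numerical and scale choices

* Eigenvalue floor for the whitening pseudo-inverse: $10^{-10}$ relative to
  the largest eigenvalue.
* Degenerate fits (zero-norm scores, zero-variance columns) raise typed
  errors; a hyperparameter pair that degenerates on some folds is excluded
  from selection with a warning, and an all-degenerate grid is an error.
* Deterministic seeding: one master seed fans out to splitting, extraction,
  and each permutation test through a fixed affine map, so reruns are
  bit-identical and no two stages share a stream.
* The bundled analysis scripts and the acceptance script run the study at
  the cohort shapes of interest (N = 1047 with families and N = 601
  unrelated; $P = 232$, $R = 38$) with two planted dimensions
  ($\rho = 0.7, 0.4$), a $3^2$ grid and 199 permutations — sizes chosen so
  a full double-direction run completes in about a minute on one core while
  keeping the smallest attainable $p$ below the corrected threshold.  The
  heavier calibration studies in the test suite (type-I error under the
  global null and under family-shared structure) use 200 replicates of 199
  permutations on small blocks, the scale at which a binomial 95% band of
  $[0.02, 0.09]$ around the nominal 0.05 is meaningful.

## A worked miniature

```{r example, message = FALSE}
spec <- synthetic_spec(n_subjects = 300, n_parcels = 25, n_seeds = 6,
                       n_behaviors = 10, n_latent = 2,
                       latent_strengths = c(0.7, 0.4), noise_sd = 0.5,
                       confound_strength = 0.2,
                       family_sizes = rep(c(1L, 2L, 3L), 50), rng_seed = 5)
young <- generate_cohort(spec, "young")
aging <- make_twin_cohort(spec, 260, rng_seed = 99, cohort_label = "aging")

cfg <- pipeline_config(grid = expand.grid(cx = c(0.5, 0.9), cy = c(0.5, 0.9)),
                       n_perm = 199, max_dims = 2, n_estimation = 60,
                       rng_seed = 11)
disc <- run_discovery(young, cfg)
disc
val <- run_validation(disc, aging, cfg)
val
```

At this miniature scale only the stronger dimension survives the
all-outer-splits rule; at the full cohort shapes both planted dimensions
are recovered (see the `analysis/` drivers).

## Known limitations

* No sparse or structured penalties, no kernel CCA; only the first singular
  pair per fit, higher dimensions exclusively via deflation.
* No site-effect harmonization and no spatial null models beyond the
  parcel-label permutation.
* The stability metric ("and stability" in model selection) is one
  reasonable choice among several and is exposed for replacement rather
  than claimed canonical.
* Inner-fold deconfounding at dimensions beyond the first operates on data
  already deflated in the outer-optimization space; re-estimating the full
  deconfound–deflate cascade per inner fold would multiply cost for a
  second-order correction and is not implemented.
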