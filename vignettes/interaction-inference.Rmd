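---
title: "Inferring directed taxon interactions from cross-sectional gradients"
author: "crossbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed taxon interactions from cross-sectional gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbeta)
```

## The model

The package treats each taxon's abundance `A_i` as a smooth function of the
measured environmental parameters `Θ_1 … Θ_m` and of the abundances of the
other taxa. Writing the change of `A_i` along a gradient as the sum of a
solitary (interaction-free) part and pairwise influence terms
`I_ij = β_ij A_i A_j`, the solitary part is eliminated by differentiating the
abundance slope with respect to a partner's abundance. Two quantities carry
all the information:

* the **slope field** `p_iαk = ∂A_ik/∂Θ_αk` — how taxon i's abundance changes
  along parameter α at sample k, and
* the **interaction field** `β_ijαk = (∂p_iαk/∂A_jk)/A_ik` — how that slope
  responds to partner j's abundance, normalized by the focal abundance.

The normalization matches generalized Lotka-Volterra (gLV) dynamics
`dA_i/dΘ = r_i A_i (1 − A_i/K_i + Σ_j B_ij A_j/K_i)`: for data generated by
such a system, the target coefficient is `β*_ij = r_i B_ij/K_i`, and the
diagonal `β_ii` captures logistic self-limitation. The ordered pairs
`(i, j)` and `(j, i)` are estimated independently — interactions may be
asymmetric in sign and strength, which no correlation-based co-occurrence
measure can express.

Because real surveys never hold the environment fixed while one taxon
varies, both fields are estimated from **cross-sample differences**: for a
fixed base sample k, the differences to all remaining samples l are
regressed, without intercept, on the corresponding parameter differences
(slope stage) or abundance differences (interaction stage). This is the
linear truncation of the multivariate Taylor expansion between samples;
second and higher orders are deliberately out of scope. Both stages come in
a `reduced` variant (only the regressors of primary interest) and a `full`
variant (parameter and abundance differences together, yielding cross-slopes
`p_ijk` and environmental sensitivities `∂p_iαk/∂Θ_α'k` as by-products). The
reduced chain is the default: it needs fewer samples per regressor and its
outputs are the ones summarized downstream.

## Assumptions and validity domain

* **Smoothness and near-linearity.** The difference regressions pool *all*
  sample pairs, so the linear truncation is applied globally, not just
  between neighbouring samples. The estimators are exact for abundances that
  are multilinear in the parameters (this is tested to 1e-6), and degrade
  gracefully for mild curvature. For strongly curved responses — e.g. a gLV
  trajectory observed along a single gradient — the slope stage returns a
  smoothed, attenuated field: informative about trends, but its sample-to-
  sample variation mixes base-point effects with true curvature. The
  consequences for validation are discussed below.
* **Identifiability requires independent variation.** On a noise-free
  dataset in which every quantity is a function of one scalar gradient, the
  influence of `Θ`, `A_i` and `A_j` cannot be separated in principle. Real
  cross-sectional designs provide the missing variation through site-to-site
  differences; the synthetic generators emulate this with per-site initial
  communities.
* **Strictly positive abundances.** `β` divides by `A_ik`; taxa with any
  zero abundance are removed up front.
* **More samples than regressors.** Checked explicitly; fewer than twice as
  many samples as variables triggers a warning.

## Preprocessing

`preprocess()` applies, in order: sample alignment by id intersection,
zero-taxon removal, uncentered unit-variance scaling (each column divided by
its n−1 standard deviation — signs and zero patterns are preserved, and the
interaction values are therefore in scaled units; the reported scale factors
allow inversion), collinearity screening of the abundance matrix, the same
for the environment matrix, and the dimension check.

The collinearity screen computes the numerical rank (singular values below
`max(dim)·ε·σ_max` count as zero) and, while rank-deficient, removes one
column drawn uniformly from the pivot-dependent set identified by
column-pivoted QR — deterministic under the supplied seed. Inside
`preprocess()` the rank is assessed **after centering** the columns: the
difference regressions cancel constant offsets between samples, so affine
relationships among columns (including the unit-sum closure of a complete
composition, which makes the abundance-difference design exactly singular)
are precisely the degeneracies that matter. The returned data stay
uncentered. `collinearity_prune()` itself defaults to the plain uncentered
test for use as a general matrix utility.

## Robust regression

All difference regressions use an iteratively reweighted Huber M-estimator
(tuning constant 1.345, the classical 95%-efficiency choice; MAD residual
scale with consistency constant 0.6745; no intercept, since the difference
of a sample with itself is exactly zero). Convergence is declared when the
largest coefficient change falls below `tol` (default 1e-6) relative to the
coefficient scale; an exact fit short-circuits, an all-zero response returns
zero coefficients, and non-convergence returns the last iterate with a
warning. The inner loop is compiled (RcppArmadillo); the R-level
`robust_fit_no_intercept()` is validated against an independent reference
M-estimator in the test suite.

## Summarization parameters

`summarize_interactions()` collapses `β_ijαk` into one value per ordered
pair:

1. **Per parameter** (`peak_median()`): exact zeros are discarded; fewer
   than `min_values = 5` non-zero values excludes the parameter. If at least
   `majority = 0.8` of the values share a sign, that is the direction;
   otherwise the parameter is excluded. The summary value `M_α` is the
   median of the values lying under the global mode of a Gaussian kernel
   density estimate (Silverman's bandwidth, `bw.nrd0`), where mode
   membership extends while the density stays above `rel_height = 0.5` of
   the peak. All four knobs are arguments.
2. **Across parameters** (`global_beta()`): if `≥ majority` of the
   qualifying `M_α` share a sign, the global value is the median of that
   group; otherwise the positive-group and negative-group medians are
   compared and the larger magnitude wins if the ratio strictly exceeds
   `ratio_threshold = 2` (a ratio of exactly two stays indeterminate);
   otherwise the pair is `indeterminate`. No qualifying parameter at all
   gives `no_qualifying_parameter`. Loosening `majority` can only move
   entries toward determinacy at each stage — a property the tests assert.

Alternative summaries are provided rather than imposed: per-parameter
weights (`weight_combine()`, e.g. ordination eigenvalues supplied by the
user — deriving them is out of scope), Euclidean norm chains
(`norm_summary()`: `β_ijk`, `β_ij`, `β_ik`, `β_i`; direction is lost by
construction), and plain mean/median/max/min (`basic_summary()`).

The peak-median procedure is conservative: it tracks the *center* of the
per-sample values, which concentrates near zero even when individual
`β_ijαk` far from the mode are large. Global values on the emulated survey
are accordingly one to two orders of magnitude smaller than the underlying
local values — a property, not a defect, shared with the published analyses
this design follows.

## Robustness machinery

`robustness_run()` re-executes the entire chain (perturbation → scaling →
pruning → slope stage → interaction stage → summarization) per iteration.
Perturbations are multiplicative uniform noise `x(1 + U(−1,1)·e)` applied to
the raw environment values, abundance values, or both; subsampling keeps
`floor(0.9·N)` sites without replacement (bootstrap resampling is
deliberately unavailable: duplicated samples put exact zeros in the
difference design). Per ordered pair, the determinate iteration values yield
a mean, a t-based 95% confidence interval, a percentile interval, and a
two-sided one-sample t-test against zero; indeterminate iterations are
dropped and counted through `n_valid`. Everything is deterministic given the
spec's seed. Error-level presets mirror the published panel
(0.01%, 0.1%, 5%, 10%, 20%, 50%).

## Synthetic generators and the validation strategy

* `make_analytic_dataset()` — abundances affine in independently drawn
  parameters; the slope field is known exactly. This is the regime where the
  slope stage's assumptions hold *exactly*, and it anchors the
  exact-recovery tests (max |error| < 1e-6).
* `make_squared_pair_dataset()` — `A_j = Θ`, `A_i = Θ²`, so
  `∂p_i/∂A_j = 2` in closed form; anchors the interaction stage.
* `simulate_glv_gradient()` — gLV dynamics integrated along the gradient
  with an adaptive Runge-Kutta scheme (relative tolerance 1e-8). With
  `site_jitter > 0`, every sample is an independent site whose initial
  community is jittered before integration to the sample's gradient
  position — the cross-sectional field design, and the source of the
  independent variation the interaction stage needs. The true slope field
  (the dynamics' right-hand side at each sampled state) and the effective
  coefficients `r_i B_ij/K_i` are stored as ground truth.
* `simulate_predator_prey()` / `simulate_mutualism()` — frozen two-species
  presets (60 sites; gradient windows covering the transient dynamics;
  asymmetric growth rates and initial abundances chosen at design time so
  the site trajectories are not mutually proportional, which the
  difference regressions require for identifiability).
* `emulate_study()` — a 150 × 17 × 13 survey-shaped community. Species
  carrying capacities follow Gaussian niche responses along a latent
  gradient with the total community capacity held constant, and a uniform
  baseline resource competition regulates total biomass; this realizes the
  regime in which overall cell numbers change little while composition
  turns over — the stated premise for analysing relative abundances at all.
  Sparse signed pairwise interactions are layered on top (matrices redrawn
  until the community coexists along the whole gradient). Three background
  species enter the closure but are not reported, so the reported
  composition is not exactly closed (a fully closed composition makes the
  abundance-difference design exactly singular — see preprocessing). The 13
  named soil parameters (pH 4–8, moisture 10–45%, nutrient and carbon
  pools) are smooth monotone functions of the latent gradient plus 8%
  measurement scatter; an optional 14th parameter (nitrate exactly
  proportional to ammonium) makes the environment matrix rank 13 for the
  collinearity benchmark.

**What the passing tests do and do not show.** The two estimation stages are
validated where their own model assumptions hold: the slope stage on
(multi)linear data, the interaction stage against the simulator's slope
field on gLV data, and their composition end-to-end on multilinear data. On
strongly curved single-gradient gLV trajectories the *composed estimated*
chain does not reliably recover interaction signs: the slope stage's global
linear truncation attenuates and distorts the local slope variation that the
interaction stage then decomposes, an effect that no parameter choice
removes (the acceptance script reports the estimated-chain recovery rate
as its own quantity, unfiltered). Interaction-sign recovery is therefore
benchmarked from the simulator's slope field (`truth_slope_field()`), which
isolates the package's defining stage; users of real data should read global
values primarily as directions and relative strengths, corroborated by the
robustness assays, rather than as unbiased estimates of gLV coefficients.
The generators also idealize real surveys in other ways: measurement noise
is multiplicative and uniform, taxa are never absent, and the environment
derives from a single latent gradient — real data have heavier-tailed
errors, structural zeros, and multi-causal environments.

## Numerical choices and degenerate inputs

* Rank tolerance `max(dim)·ε·σ_max`; random column removal seeded and
  restricted to QR pivot-dependent columns.
* IRLS: `tol = 1e-6` on coefficient change, `max_iter = 100`; exact fits
  short-circuit; all-zero responses yield zero coefficients rather than
  errors (a constant slope field then gives an all-zero interaction row, as
  it should).
* Even-count medians are midpoint means; KDE bandwidth `bw.nrd0` with 512
  grid points; a degenerate (constant) value set returns that value as its
  peak median without a density call.
* Relative-abundance row sums above `1 + 1e-6` are errors; sums below 1 are
  only a warning, because taxon filtering legitimately breaks closure.
* Ties in the majority rule at threshold 0.5 fall through to the
  magnitude-ratio rule; a ratio of exactly 2 stays indeterminate.
* `j = i` is included among the interaction regressors — the diagonal
  `β_ii` is the biologically meaningful self-limitation term.
* Subsampled robustness iterations recompute scaling and pruning from the
  subsample; when a precomputed slope field is supplied it is restricted to
  the retained samples but keeps the full-data scale factors (a deliberate,
  sign-preserving approximation).

## Problem sizes

The shipped tests and the acceptance script use 40–80 samples for the
analytic constructions, 60 sites for the two-species communities (50 seeds
for the noisy recovery rates), 100 robustness iterations per error level,
20 subsampling iterations, and the full 150 × 17 × 13 emulation for the
survey-scale pipeline, chosen so the complete validation cycle runs in a few
minutes on one CPU while leaving every statistical claim with a comfortable
margin.

## Known limitations

* Second-order Taylor terms, time-series (LIMITS-style) inference, and the
  solitary term `S_i` itself are out of scope.
* Global values inherit the conservatism of the peak-median summarization;
  comparing magnitudes across datasets requires identical scaling choices.
* Unmeasured environmental drivers bias inferred interactions, a
  limitation intrinsic to the cross-sectional design: the method separates
  biotic from abiotic effects only for the parameters it is given.
* The compositional (closure) approximation is trustworthy for diverse,
  even communities with regulated total biomass; for low diversity or
  dominance-structured communities the relative-abundance analysis can
  diverge from the absolute-abundance one.
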