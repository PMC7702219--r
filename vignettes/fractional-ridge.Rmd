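---
title: "Fractional ridge regression: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional ridge regression: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frridge)
```

## The model and its reparameterization

Ridge regression estimates the coefficients of the linear model
$y = X\beta + \epsilon$ by penalizing their squared L2-norm,

$$\hat\beta(\alpha) = (X^\top X + \alpha I)^{-1} X^\top y,$$

with $X$ a $d \times p$ design (rows are data points) and, throughout
this package, $Y$ a $d \times t$ matrix of many targets sharing the
design — the typical shape of voxelwise encoding models, mass-univariate
genomics screens, and similar many-response regressions.

Write the SVD as $X = U \Lambda V^\top$ with singular values
$\lambda_1 \ge \dots \ge \lambda_r > 0$. In the rotated coordinates
$\tilde y = U^\top y$, $\tilde\beta = V^\top\beta$, ordinary least
squares is the componentwise division
$\tilde\beta^{OLS}_i = \tilde y_i / \lambda_i$ and ridge regression is
componentwise shrinkage

$$\tilde\beta_i(\alpha) = \frac{\lambda_i^2}{\lambda_i^2 + \alpha}\,
  \tilde\beta^{OLS}_i,$$

so components along small singular values are shrunk first. Because
$V$ has orthonormal columns, norms computed in the rotated space equal
norms in predictor space.

The package's hyperparameter is not $\alpha$ but the norm fraction

$$\gamma(\alpha) = \frac{\lVert\tilde\beta(\alpha)\rVert_2}
  {\lVert\tilde\beta^{OLS}\rVert_2} \in [0, 1],$$

a monotone, scale-free, per-target reindexing of the regularization
path: $\gamma = 1$ is the unregularized (pseudoinverse) solution and
$\gamma = 0$ the zero solution. $\gamma(\alpha)$ depends on both the
spectrum and the target, so except in special cases there is no closed
form for the $\alpha$ achieving a requested $\gamma$; the solver finds
it numerically.

## The algorithm

For a call `frr(X, Y, fracs)`:

1. decompose the design once (`frr_decompose`); for $d > p$ the
   singular values and $V$ come from the eigendecomposition of the
   $p \times p$ Gram matrix $X^\top X$, which is cheaper than a full
   SVD and gives the same decomposition;
2. rotate all targets in one product $\tilde Y = U^\top Y$ and form all
   rotated OLS solutions by one broadcast division;
3. build the candidate penalty grid (`frr_alpha_grid`): log-spaced from
   $10^{-3}\lambda_r^2$ to $10^{3}\lambda_1^2$ — far enough below and
   above the squared spectrum that achieved fractions cover essentially
   $(0,1)$ — at 0.2 log$_{10}$ spacing;
4. tabulate the shrinkage factors
   $\lambda_i^2/(\lambda_i^2+\alpha_j)$ once for the whole grid
   (`frr_shrinkage_factors`); they are target-independent;
5. per target, evaluate the fraction curve $\gamma_j$ on the grid
   (`frr_gamma_curve`), interpolate the penalties $\alpha^*$ for the
   requested fractions (`frr_interpolate_alphas`), and apply the
   shrinkage at those penalties (`frr_solve_target`);
6. back-rotate every solution of every target in a single
   multiplication by $V$ (`frr_unrotate`).

The expensive steps — decomposition and back-rotation — are done once
regardless of $t$, which is what makes the method practical for tens of
thousands of targets.

## Tunable parameters

* `fracs` (default `seq(0, 1, by = 0.05)`): the requested fractions.
  Dimensionless; duplicates are solved once and output follows the
  caller's order.
* `log_spacing` (default 0.2 log$_{10}$ units): grid resolution. At
  0.2 the interpolated fractions land within about 1% of the request
  (about 0.3% in the benchmark scenarios); halving the spacing roughly
  quarters the deviation at double the grid cost. There is rarely a
  reason to touch it.
* `tol` (default `max(d, p) * .Machine$double.eps`, relative to
  $\lambda_1$): singular-value truncation, the standard pseudoinverse
  convention. Values below it are treated as exact zeros, which defines
  the rank, the OLS norm, and therefore the meaning of $\gamma$ on
  rank-deficient designs.
* `standardize`: `"none"` (default), `"center"` (subtract predictor and
  target means; predictions add them back, giving an implicit
  intercept), or `"zscore"` (also scale predictors to unit SD; the
  fraction then refers to the standardized coefficients). No explicit
  intercept column is ever added: centering is the supported route, so
  $\gamma$ stays a statement about predictor coefficients only.

## Numerical choices

* **Interpolation variable.** The solver interpolates
  $\log_{10}\alpha$ piecewise-linearly *as a function of* $\gamma$.
  The curve $\gamma(\log\alpha)$ is smooth and near-linear through its
  transition region, so this direction needs no numerical inversion and
  is accurate on a 0.2-decade grid; the ~1% accuracy property is
  verified in the test suite. Inputs are sorted by construction and the
  interpolation assumes sortedness.
* **Endpoints.** Requested $\gamma = 1$ bypasses interpolation and
  returns the rotated OLS solution with $\alpha^* = 0$ exactly;
  $\gamma = 0$ returns exact zeros with the sentinel
  $\alpha^* = \infty$ (serialized as the string `"inf"` in TSV
  output). A requested fraction above the largest grid-achieved
  fraction (possible because the grid minimum is positive) is linearly
  extrapolated in the same coordinates.
* **Grid lattice.** Grid endpoints are snapped *outward* onto integer
  multiples of the spacing, so any two designs with the same
  singular-value range get the identical grid — one fewer source of
  run-to-run variation.
* **Degenerate targets.** A target whose OLS solution has zero norm
  makes $\gamma$ a 0/0; every penalty yields the same zero solution.
  Such targets get zero coefficients at all fractions and `NaN` markers
  for $\alpha^*$ and the achieved fraction.
* **Gram-route truncation.** Eigenvalues of $X^\top X$ carry numerical
  noise at the scale $\epsilon\lambda_1^2$, so the Gram route truncates
  on the eigenvalue scale; a spurious eigenvalue of order
  $\sqrt{\epsilon}\,\lambda_1$ would otherwise survive a threshold
  stated on the singular-value scale.
* **Cross-validation ties.** `frr_cv` breaks ties in test-$R^2$ toward
  the smallest fraction — the most regularized of the tied solutions, a
  parsimony default. Only single-split selection is implemented; how to
  aggregate over multiple splits (pooling, refitting, averaging) is
  left to the caller, who controls the split and its seed.

## Special-case identities (the `theory` helpers)

When the spectrum is flat ($\lambda_i \equiv \lambda$, e.g. orthonormal
columns scaled by $\lambda$), the fraction has the closed form
$\gamma = \lambda^2/(\lambda^2+\alpha)$ and its inverse
$\alpha = \lambda^2(1/\gamma - 1)$ (`flat_spectrum_gamma`,
`flat_spectrum_alpha`). These never short-circuit the main solver; they
are kept as independent oracles — the tests require the general
algorithm to reproduce them within the 2% interpolation tolerance.
`effective_dof` computes $\sum_i \lambda_i^2/(\lambda_i^2+\alpha)$, the
effective degrees of freedom of the ridge fit, useful for re-expressing
a heuristic $\alpha$ grid on an interpretable axis.
`l1_fraction_rotated` is the equal-coefficient special case of L1
shrinkage and equals `effective_dof / p`; note it is an L1 statement
about the *rotated* coefficients, not the original ones.

## What the simulation harness emulates

`frr_scenario` / `make_correlated_design` / `simulate_targets` generate
the benchmark conditions used throughout the tests: a $d \times p$
standard-normal design in which correlation is induced by $2p$ rounds
of "pick two predictors at random, replace the first by their sum plus
fresh noise", followed by z-scoring each column (population SD, so the
unit-variance invariant is exact); Gaussian ground-truth coefficients
(`beta_sd = 1`); and additive Gaussian noise whose SD, by default,
matches each target's signal SD (`"match-signal"`, an SNR of 1 — the
noise level is otherwise a free parameter, and the harness exposes it).
The two standard scenarios are $d = 100$, $p = 5$ (tall, easy) and
$d = 100$, $p = 100$ (square, strongly regularization-dependent). All
randomness flows from the scenario's single integer seed; the design
uses `seed` and the coefficient/noise draws use `seed + 1`, two fixed
streams so either piece can be regenerated independently.

What these simulations are *not*: real measurements. They have
Gaussian noise, exchangeable targets, stationary correlation structure,
and no temporal autocorrelation, outliers, or heteroscedasticity.
Passing tests on them demonstrates the solver's numerical claims
(fraction accuracy, oracle equivalence, endpoint exactness) and the
qualitative contrast with a conventional log-spaced $\alpha$ grid —
whose levels pile up at fraction ≈ 0 and ≈ 1 while the fractional
parameterization covers the path evenly (`compare_frr_srr`) — not that
any particular fraction is right for a given real data set.

The standard-ridge baselines come in two deliberately different
implementations: `srr_solve_naive` (a fresh pseudo-inversion per grid
penalty) and `srr_solve_rotated` (one SVD, scalar shrinkage per
penalty). They produce the same solutions and serve as each other's
cross-check; `ridge_direct` plays the same oracle role for the
fractional solver itself.

## Problem sizes in the test suite

The suite runs the full benchmark scenarios at their native size
($d = 100$, $p \in \{5, 100\}$, 10 targets, 10 seeds) — the method is
cheap enough that nothing needs scaling down — plus a spread of small
problems ($d \in \{10, 50\}$, $p \in \{3, 10, 60\}$, including $p > d$)
for the oracle-equivalence and property checks. The whole suite
completes in well under a minute.

## Known limitations

* Only the L2 (ridge) penalty: no lasso or elastic-net variants, whose
  solution norms are not monotone reparameterizations of a scalar
  penalty in the same way.
* No generalized cross-validation; fraction selection is single-split
  CV with an explicit seed.
* The fraction is defined against the pseudoinverse OLS norm; on
  rank-deficient designs that is the minimum-norm solution, and the
  truncation tolerance (documented above) is part of the definition.
* Interpolation accuracy is an empirical ~1% guarantee at the default
  spacing, not an error bound; pathological spectra spanning many more
  decades than the grid assumes would need a finer `log_spacing`.
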