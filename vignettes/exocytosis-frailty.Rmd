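---
title: "Modeling single-granule exocytosis: piecewise hazards, a discrete IRP frailty, and cluster-robust likelihood inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling single-granule exocytosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exofrailty)
```

## The data model

A pulsed-depolarization imaging experiment follows the docked secretory
granules of several cells. Each granule contributes one right-censored
observation: the time of its exocytosis, or the end of observation
(administrative censoring — the same censoring time for every granule).
Granules of one cell form a statistical cluster; the cell-level binary
covariate distinguishes healthy from diabetic donors and is constant
within a cell.

Time zero is the onset of the first pulse. The default protocol —
`stim_protocol()` — is ten 1-second pulses every 10 seconds with
observation ending at 100 s. Pulse intervals are half-open,
`[s, s + 1)`: a granule releasing exactly when a pulse ends is counted
in the following rest interval. The end of observation is a package
convention (ten full 10-second cycles); the protocol object makes it
configurable because an experiment's censoring time is a property of
the recording, not of the model.

## Two models of the same hazard

**Piecewise-constant hazard (Poisson form).** The hazard is constant
within the first pulse (rate `rho0`), within later pulses (`rho1`) and
between pulses (`rho2`), each multiplied by `exp(beta_k X)` for
diabetic cells. `episode_split()` cuts each granule's follow-up at
segment boundaries; since each granule has at most one event, the
resulting exposure table has exactly the piecewise-exponential
survival likelihood as its Poisson likelihood, and
`fit_piecewise_exponential()` maximizes it with `glm`. The package
asserts this identity numerically rather than assuming it.

**Discrete frailty.** The elevated first-pulse rate admits a different
mechanistic reading: a small immediately releasable pool (IRP) of
granules with an `eta`-fold higher rate, exhausted early. Conditional
on the unobserved pool membership (frailty `Z` in `{1, eta}` with
`P(Z = eta | X) = pi_X`), the baseline is the same in every pulse
(`rho0 = rho1` by constraint) and diabetes acts only between pulses
(`beta1 = 0`). Averaging the conditional likelihood over the two-point
frailty law gives the marginal per-granule contribution

```
l_ij = log[ mu0(t|X)^d ( pi_X eta^d e^{-eta M0(t|X)}
                         + (1 - pi_X) e^{-M0(t|X)} ) ]
```

and the working-independence log-likelihood `l_I` sums these over all
granules, deliberately ignoring the within-cell correlation.

## Parameters, units, defaults

| parameter | meaning | scale used internally |
|---|---|---|
| `rho1 = exp(alpha1)` | pulse rate, s^-1 | log |
| `rho2 = exp(alpha2)` | between-pulse rate, s^-1 | log |
| `beta2` | log hazard ratio of diabetes between pulses | identity |
| `eta` | IRP rate ratio (dimensionless, > 1 expected) | log |
| `pi0`, `pi1` | IRP probability per group | identity, bounded [0, 1] |

The working vector is `theta = (alpha1, alpha2, beta2, log eta, pi0,
pi1)`. Logs symmetrize the profile likelihoods of the strictly
positive parameters. The pool probabilities stay on their natural
scale: this was a genuinely open design choice (a logit transform also
symmetrizes), settled by the boundary test. The null `pi_X = 0` must
be a *finite* working value for the adjusted likelihood-ratio test
below — under a logit transform the null sits at minus infinity, and
the constrained maximization along the adjustment transform
degenerates to the unadjusted test as the constraint value diverges,
silently erasing the clustering correction. Identity scale keeps the
boundary test well posed; `eta <= 1` solutions are not excluded, only
flagged.

## Cluster-robust inference

The Hessian of `l_I` understates uncertainty because granules within a
cell are correlated. `sandwich_variance()` computes
`R = H^-1 V H^-1` with `V` the sum of outer products of per-cell score
vectors (analytic gradients, summed within cells;
`score_by_cluster()` provides the generic numerical route and the two
agree to numerical precision in the test suite).
`build_adjustment()` then forms the adjusted log-likelihood

```
l_A(theta) = l_I( theta_hat + C (theta - theta_hat) ),   C = N^-1 N_A
```

with `N` and `N_A` symmetric spectral square roots of `-H` and `R^-1`
(the positive-definite forms; the observed-information sign convention
is the only one with real square roots). `l_A` keeps the same optimum
but acquires curvature `-R^-1` there, so likelihood-ratio statistics
computed from it account for clustering. Tests of interior nulls use
the chi-square with 1 df; tests of `pi_X = 0` use the one-sided
mixture `(chi2_0 + chi2_1)/2`, with the statistic identically zero
when the estimate already sits on the boundary. Confidence intervals
are profile-likelihood intervals on `l_A` found by bracketing and
bisection on the working scale; a profile that reaches a natural bound
(`pi = 0` or `1`) before crossing the deviance threshold is reported
one-sided with a warning rather than extrapolated. For the Poisson
model's Wald tests a t reference with J − 1 degrees of freedom is
used; the df convention for cluster-corrected t tests is not uniquely
determined by theory, and J − 1 is the package's documented choice.

## The synthetic-data generator

`simulate_dataset()` emulates the study structure: 11 healthy and 8
diabetic cells by default, a configurable number of granules per cell
(default 100 — experiments do not report per-cell granule counts, and
about a hundred docked granules in a TIRF footprint is a realistic
order of magnitude; the value is recorded in the truth sidecar, never
asserted as fact), granule-level two-point frailties, and exact
inverse-transform sampling of event times: within a protocol segment
the cumulative hazard is linear, so `multiplier * M0(t) = -log(u)` is
inverted segment by segment in closed form.

Within-cell correlation is induced by a cell-level multiplicative
factor `w ~ Gamma(mean 1, variance v)`, default `v = 0.5`. Two points
matter. First, the fitted model *omits* `w` on purpose: the generator
reproduces the real situation in which clustering is unmodeled and
handled purely by robust inference. Second, a mean-one gamma is the
standard shared-frailty convention; any mean-one nonnegative law would
serve. Draws consume the generator in a fixed order (per cell: the
cell factor, then the granule frailties, then the granule uniforms) so
a seed fully determines the dataset.

What the generator does **not** emulate: cell-to-cell variation in IRP
*content* (each granule's pool membership is an independent coin with
the same `pi_X` in every cell), time-varying calcium input,
fluorescence noise, or detection error. Consequences below.

## Numerical choices

* Likelihood evaluation collapses granules with identical sufficient
  statistics (all censored granules of a covariate group share one
  weighted row), making an evaluation O(number of events).
* The mixture is computed relative to the larger exponent
  (log-sum-exp); with `eta ~ 500` and `M0 ~ 2` the IRP term underflows
  naive arithmetic. Evaluation tolerates `pi` slightly outside [0, 1]
  as long as the mixture stays positive, because the adjustment
  transform can map working points marginally outside the natural
  domain; truly invalid points receive a large finite penalty so the
  optimizer's line search can recover.
* Optimization: `nlminb` with the analytic gradient, from a start grid
  crossing the no-frailty fit with `eta` in {10, 100, 1000} and `pi`
  in {0.005, 0.02, 0.1}; best local optimum kept, all starts recorded.
  Convergence is judged by the gradient norm (below 1e-5 relative to
  the objective) over coordinates not pinned at a bound; `pi` within
  1e-6 of a bound is flagged as a boundary solution.
* Derivatives: the observed Hessian is a Richardson-extrapolated
  central-difference Jacobian of the analytic gradient; the generic
  numerical scores use the same scheme. Steps scale with coordinate
  magnitude, or with the robust standard error where curvature checks
  demand it.

## Problem sizes in the test suite

The suite validates parameter recovery on 20 replicates of 200 cells
times 150 granules at the frailty-report values with `v = 0`
(estimator correctness under the assumed model: with `v > 0` the
independence MLE targets a pseudo-true value, and truth-coverage is
not the estimator's contract), and test calibration on 200 replicates
of 120 cells times 100 granules with `v = 0.5` under the null
`pi1 = 0`. The calibration design uses more cells than the original
study because the sandwich estimator needs a moderate number of
clusters to be stable; with only 19 cells its own sampling noise
dominates and the adjusted test over-rejects.

## Known limitations

* **Few clusters.** With ~19 cells the sandwich variance is noisy; the
  adjusted test can then be anti-conservative itself. Nothing in the
  method repairs this; the package flags non-positive-definite
  adjustment inputs instead of proceeding.
* **Heterogeneity channel.** Because the generator's cell factor
  scales all hazards proportionally, it inflates the variance of
  rate-parameter scores (dense events) but barely correlates the
  `pi1`-scores, which are driven by rare first-pulse events. Passing
  calibration tests therefore demonstrate robustness to *this*
  clustering mechanism; real data in which cells differ in IRP content
  would stress the `pi` tests harder, and the generator cannot produce
  that regime.
* Boundary-adjacent `pi` estimates give one-sided profile intervals;
  the package reports them as such rather than guessing a two-sided
  form.
* No left truncation, no competing risks, and only piecewise-constant
  baselines; the Cox formulation is out of scope.
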