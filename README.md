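# exofrailty

Time-to-event analysis of single-granule exocytosis with a discrete
frailty for the immediately releasable pool (IRP), and cluster-robust
likelihood inference.

## The problem

TIRF microscopy can follow individual insulin-containing secretory
granules at the plasma membrane of pancreatic beta-cells and record the
moment each granule fuses (exocytosis). Under a train of brief
depolarizing K+ pulses, each granule yields a classic right-censored
time-to-event observation: either its exocytosis time, or the end of the
experiment. Two features make naive analysis wrong:

* **Heterogeneity** — a small immediately releasable pool of granules
  releases far faster than the rest, which no image can identify in
  advance; and
* **Clustering** — granules of the same cell are correlated ("highly
  responding" cells), so independence-based standard errors and
  p-values are too small.

`exofrailty` implements the full analysis pipeline for such data, plus a
synthetic-data generator with the same statistical structure so every
stage is testable without any microscope.

## Models

**Piecewise-constant hazard (Poisson form).** With segments k = 0 (first
pulse), k = 1 (later pulses), k = 2 (between pulses) and diabetes
covariate X:

    mu(t | X) = exp(alpha_k + beta_k X),   rho_k = exp(alpha_k)  [s^-1]

fitted by `glm` on the episode-split exposure table, with naive and
cell-clustered sandwich variances.

**Discrete IRP frailty.** Conditional on an unobserved frailty Z,

    mu(t | X, Z) = Z mu0(t | X),  P(Z = eta | X) = pi_X,  P(Z = 1 | X) = 1 - pi_X

with a common pulse rate rho1 across pulses, a between-pulse rate
rho2 e^{beta2 X}, frailty ratio eta and IRP probabilities pi_0, pi_1.
The marginal survival is the mixture

    S(t | X) = pi_X exp(-eta M0(t|X)) + (1 - pi_X) exp(-M0(t|X)),

with M0 the cumulative baseline hazard. The marginal (working
independence) log-likelihood l_I is maximized directly; valid inference
under clustering uses the sandwich variance R = H^-1 V H^-1 over
per-cell scores and the Chandler–Bate adjusted log-likelihood
l_A(theta) = l_I(theta_hat + C (theta - theta_hat)), whose curvature at
the optimum equals -R^-1. Likelihood-ratio tests of boundary nulls
(pi_X = 0) use the one-sided mixture reference (chi2_0 + chi2_1)/2;
confidence intervals are profile-likelihood intervals on l_A.

## Worked example

Simulate a study-sized dataset (19 cells: 11 healthy, 8 diabetic; 120
granules each) and run both models:

```r
library(exofrailty)

design <- simulation_design(granules_per_cell = 120)
gd <- simulate_dataset(design, seed = 42)
gd
#> Granule event dataset: 2280 granules in 19 cells (clusters)
#>   events: 113  censored: 2167
#>   cells by covariate: healthy = 11 , diabetic = 8

print(summary(fit_piecewise_exponential(gd)), digits = 3)
#>   parameter  estimate     lower     upper        p  p_naive
#> 1      rho0  0.016076  0.010043  0.025733 1.88e-06 1.45e-06
#> 2      rho1  0.001833  0.001145  0.002936       NA       NA
#> 3      rho2  0.000183  0.000103  0.000326 2.11e-06 6.50e-07
#> 4     beta0 -1.348163 -2.437230 -0.259095 2.60e-02 2.37e-02
#> 5     beta1 -0.652958 -1.640815  0.334900 2.12e-01 1.33e-01
#> 6     beta2  0.905564  0.062060  1.749067 4.97e-02 3.72e-03

fit <- fit_frailty(gd)
print(frailty_table(fit), digits = 3)
#>   parameter estimate    lower    upper        p  p_naive converged
#> 1      rho1 1.22e-03 7.62e-04 1.87e-03       NA       NA      TRUE
#> 2      rho2 1.12e-04 5.93e-05 1.96e-04 2.26e-18 8.87e-18      TRUE
#> 3     beta2 1.36e+00 5.92e-01 2.14e+00 5.51e-04 4.17e-06      TRUE
#> 4       eta 8.73e+02 5.68e+02 1.35e+03 2.52e-17 1.10e-19      TRUE
#> 5       pi0 2.52e-02 1.34e-02 3.86e-02 5.31e-06 9.83e-20      TRUE
#> 6       pi1 3.67e-03 0.00e+00 9.84e-03 2.50e-02 3.51e-02      TRUE
```

Reading the frailty table: granules release at ~0.0012 s^-1 during
pulses and ~0.0001 s^-1 between them; IRP granules release eta-fold
(here ~900-fold) faster; an estimated 2.5% of docked granules in healthy
cells belong to the IRP against 0.4% in diabetic cells (the profile
interval for `pi1` touches 0: a boundary-adjacent estimate, reported
one-sided). `p` columns are cluster-adjusted likelihood-ratio tests
(rate rows test equal pulse/between rates; `pi` rows are one-sided
boundary tests); `p_naive` ignores clustering and is visibly
anti-conservative (compare `pi0`: 1e-19 naive vs 5e-6 adjusted).
Converting pool probabilities to granule counts:

```r
docked_granule_count(capacitance_pF = 10, specific_capacitance_fF_um2 = 10,
                     density_per_um2 = 0.8)
#> [1] 800
irp_granule_count(800, fit$params$pi0)
#> [1] 20.12484
```

Model-vs-data overlays (Kaplan–Meier band, marginal incidence and its
IRP / non-IRP components) come from `curves_table(fit$params, gd)`.

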