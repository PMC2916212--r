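# mnarsens

Bayesian selection models and sensitivity analysis for continuous trial
outcomes that may be **missing not at random (MNAR)**.

When a randomized trial loses outcome data, every analysis rests on an
untestable assumption about *why* scores are missing. This package is
for trial statisticians who want to do better than asserting
missingness at random (MAR): it fits a joint Bayesian selection model
in which MAR is one point in a parameterised family, and then explores
departures from it using every source of ancillary information a
well-designed trial can collect — elicited prior beliefs, carer-reported
proxy outcomes, and the record of repeated contact attempts.

## The model

Trial variables are modelled in causal order — centre $X$, baseline
score $Y_0$, its response indicator $R_0$, randomized arm $T$, final
score $Y_1$, its indicator $R_1$, optionally a proxy score $Z$ with
indicator $R_Z$ — each regressed on all earlier variables: normal
regressions for scores, logistic regressions for indicators. With
$\delta_{A,B}$ the coefficient of $A$ in the model for $B$, the key
unidentified quantity is $\delta_{Y_1,R_1}$, the log-odds of response
per (observed-data) SD of the possibly unobserved final score. The
package supports:

* **MAR and delta-constrained fits** (`run_mar()`, `run_delta_grid()`):
  fix $\delta_{Y_0,R_0}$ and $\delta_{Y_1,R_1}$ over a grid (including
  arm-specific worst cases) and track the treatment effect
  $\delta_{T,Y_1}$ and $\Delta(Y_1,\text{arm})$ — the posterior mean of
  imputed missing final scores minus the observed mean.
* **Pattern-mixture conversion**: for equal-variance normal patterns,
  a mean difference $\mu_o-\mu_m$ equals a logistic slope
  $b=(\mu_o-\mu_m)/\sigma^2$ (`pattern_mixture_to_selection()`), which
  is how elicited beliefs about score differences become selection
  priors.
* **Prior elicitation arithmetic** (`pool_opinions()`,
  `moments_from_weights()`, `prior_for_delta()`,
  `correlation_from_anchors()`): linear opinion pooling of 9-category
  expert weight tables and conversion to per-SD slope priors, used
  directly in `run_elicited()`.
* **Proxy outcomes** (`run_proxy_suite()`): identification of
  $\delta_{Y_1,R_1}$ from a conditional-independence assumption on the
  proxy, including the failure mode when the proxy is weakly
  correlated with the outcome.
* **Repeated contact attempts** (`run_attempts_suite()`): a
  shared-coefficient logistic model across attempts ("continuum of
  resistance") under which the outcome-selection coefficient becomes
  identifiable.
* **A forward simulator** (`simulate_trial()`, `quatro_sim_params()`)
  calibrated to the published margins of a four-centre schizophrenia
  adherence-therapy trial (409 participants), so every stage can be
  validated against known truth.

Fitting is by data-augmentation MCMC written for this package
(conjugate Gibbs for the normal blocks, preconditioned random-walk
Metropolis for the logistic blocks, exact-Gibbs imputation under MAR),
with Gelman–Rubin diagnostics (`gelman_rubin()`), broom-style `tidy()`
/ `glance()` methods and `autoplot()` graphics.

## Worked example

Simulate a 409-participant trial from the calibrated generator and run
a three-point sensitivity analysis on the outcome-selection slope:

```r
library(mnarsens)

sim <- simulate_trial(quatro_sim_params(), seed = 409)
missingness_pattern(sim$data)
#> # A tibble: 5 × 4
#>   pattern       intervention control total
#>   <chr>                <int>   <int> <int>
#> 1 baseline only           31      14    45
#> 2 final only              11      12    23
#> 3 neither                  2       0     2
#> 4 both                   163     176   339
#> 5 total                  207     202   409

cells <- run_delta_grid(sim$data,
  grid = list(A = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0),
              D = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0.5),
              E = c(delta.Y0.R0 = 0, delta.Y1.R1 = 1)),
  mcmc = mcmc_config(n_chains = 2, n_burn = 1000, n_keep = 1500, seed = 11))
render_report(cells)
#> Model  Fixed deltas                          Delta(Y1,T)   Delta(Y1,C)   Effect
#> A      delta.Y0.R0 = 0, delta.Y1.R1 = 0      -0.53 (2.09)  1.09 (3.04)   1.50 (1.15)
#> D      delta.Y0.R0 = 0.0, delta.Y1.R1 = 0.5  -4.98 (2.15)  -3.49 (3.10)  1.14 (1.15)
#> E      delta.Y0.R0 = 0, delta.Y1.R1 = 1      -9.39 (2.10)  -8.42 (3.09)  0.84 (1.21)
```

Reading the table: under the near-MAR model A the fitted model implies
missing final scores essentially like observed ones
($\Delta(Y_1,\cdot)\approx 0$). Assuming instead that a one-SD-lower
final score halves or quarters the odds of response
($\delta_{Y_1,R_1}=0.5, 1$) pushes the implied missing-score means
about 5 and 9 points below the observed means, and drags the treatment
effect down with it — here by about 0.7 points across the grid, small
against the posterior SD of 1.2. (This realization's generating effect
is −0.4; at n = 409 the effect posterior has SD ≈ 1.15, so the
credible interval comfortably covers it.) Elicited priors enter the
same machinery:

```r
pooled <- combine_arms(c(-2.9, 5.7), c(-2.1, 5.2))   # pooled mean -2.5
prior  <- prior_for_delta(pooled$mean, pooled$variance_rounded, 10)
prior
#> # A tibble: 1 × 2
#>    mean variance
#>   <dbl>    <dbl>
#> 1  0.25      0.3
run_elicited(sim$data, prior)
```

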