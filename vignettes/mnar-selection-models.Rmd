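---
title: "Exploring informatively missing trial outcomes with joint selection models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring informatively missing trial outcomes with joint selection models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A two-arm randomized trial measures a continuous quality-of-life score
(the SF-36 mental health component score, MCS; higher is better) at
baseline and at follow-up. Some participants provide no baseline score,
more provide no final score, and the final-score loss is imbalanced
across arms. Any analysis must then rest on untestable assumptions
about why scores are missing. The usual starting point is missingness
at random (MAR): conditional on everything observed, the probability of
a missing score does not depend on the score itself. `mnarsens`
implements a joint Bayesian selection model in which that assumption is
a *parameterised special case*, so that departures from MAR can be
explored systematically — through fixed sensitivity coefficients,
through priors elicited from the investigators, through carer-reported
proxy outcomes, and through the record of repeated contact attempts.

## The joint model

Variables are modelled in causal order: centre $X$ (four categories),
baseline score $Y_0$, its response indicator $R_0$, randomized arm $T$
(independent of everything before it), final score $Y_1$, its response
indicator $R_1$, and optionally the carer proxy score $Z$ with
indicator $R_Z$. Each variable is regressed on all earlier ones:
normal linear regressions for scores, logistic regressions for
indicators. Writing $\delta_{A,B}$ for the coefficient of $A$ in the
model for $B$ (the package's `delta.A.B` naming), the final-response
model is

$$\operatorname{logit} P(R_1 = 1) = \delta_{0,R_1} + \delta_{X,R_1}'X +
\delta_{Y_0,R_1} \tilde Y_0 + \delta_{R_0,R_1} R_0 + \delta_{T,R_1} T +
\delta_{Y_1,R_1} \tilde Y_1,$$

where tildes denote standardization by the observed-data mean and the
SD pooled within centres. Because $\tilde Y_1$ may be unobserved
exactly where $R_1 = 0$, the coefficient $\delta_{Y_1,R_1}$ — the
change in log-odds of response per SD of the final score — is not
identified by the data; it is the sensitivity parameter. Setting
every score-to-indicator and indicator-to-score arc to zero
(`spec_mar()`) recovers MAR.

Standardizing the scores in the selection regressions serves two
purposes: the sampler is better conditioned, and $\delta_{Y_1,R_1}$ has
the interpretable per-SD scale on which beliefs were elicited. The
standardizer is frozen from the observed data once per analysis and
applied unchanged to imputed scores inside the sampler, so the meaning
of the coefficient never drifts with the imputations.

### Pattern-mixture connection

For a normal score with common SD $\sigma$ in responders and
non-responders, a mean difference $\mu_o - \mu_m$ between the patterns
is equivalent to a logistic selection slope $b = (\mu_o -
\mu_m)/\sigma^2$ per raw unit, i.e. $(\mu_o - \mu_m)/\sigma$ per SD
(`pattern_mixture_to_selection()`). This identity is what converts
elicited beliefs about *differences in means* into priors or fixed
values for $\delta_{Y_1,R_1}$: a belief that non-responders score 2.5
points lower at reference SD 10 corresponds to a per-SD slope of 0.25.

### Elicitation arithmetic

Experts distribute a weight of 100 over nine categories of the
non-responder minus responder difference (from "lower by 13 or more"
to "higher by 13 or more"). `pool_opinions()` averages weight vectors
(a linear opinion pool), `moments_from_weights()` extracts moments via
the category midpoints (±14.5 for the open-ended extremes), and
`prior_for_delta()` converts to the selection scale. The anchoring
question for between-arm correlation is interpreted by linear
interpolation (`correlation_from_anchors()`): an unchanged guess is
correlation 0, revision to the maximum is 1. Elicited correlations are
reported per expert but deliberately not pooled: a set like
(0, 0, 0, 0.29, 0.73, 1) is not usefully summarised by one number, so
the package instead offers the two contrasting analyses — a common
slope prior, or independent arm-specific priors
(`run_elicited(prior_mode = )`).

### Proxy outcomes

With proxies, $Z$ is regressed on all model variables
(main effects only) and $R_Z$ on those plus standardized $Z$. One
additional conditional-independence assumption —
$\delta_{R_1,Z} = 0$, i.e. the act of responding does not itself shift
the carer's assessment — makes $\delta_{Y_1,R_1}$ identifiable.
`run_proxy_suite()` exercises this identification and its failure
mode: when the proxy is only weakly correlated with the outcome, the
observed $R_1$–$Z$ association must be explained through the
$Y_1$–$R_1$ arc, inflating the slope estimate badly. The package's
tests reproduce this direction on synthetic data with complete-case
correlation calibrated to 0.31.

### Repeated contact attempts

When each contact attempt is recorded, the single $R_1$ regression can
be replaced by a logistic model for success of the $m$-th attempt in
which *only the intercepts* $\alpha_m$ depend on $m$; all slopes —
attempt type, centre, arm, standardized $Y_0$ and $Y_1$, optionally an
arm-by-outcome interaction — are shared across attempts. This
"continuum of resistance" assumption makes the outcome coefficient
identifiable: hard-to-reach responders stand in for non-responders.
Centre-by-attempt-index dummies are included only for attempts 2 and 3,
because later attempts are too rare to support them. With a single
allowed attempt the model reduces exactly to the single-logistic model,
a property the test suite asserts as a likelihood identity.

## Posterior computation

`fit_selection_model()` samples the joint posterior of parameters and
missing scores by data augmentation:

* **Normal-regression blocks** (coefficients and variances of the
  $Y_0$, $Y_1$, $Z$ models) use conjugate Gibbs updates; precisions
  have gamma(0.001, 0.001) priors. The Student-t option for $Y_1$
  (df fixed at 10 or 5, never estimated) is handled by the normal
  scale-mixture representation with per-observation latent weights, so
  conjugacy is preserved; `sigma2.Y1` is then the squared scale.
* **Logistic blocks** use random-walk Metropolis with a multivariate
  normal proposal preconditioned by the Fisher information at
  initialization, and a global scale adapted toward acceptance ~0.28
  during burn-in only (so the kept draws come from a fixed kernel).
  The high-dimensional attempts block receives five proposals per
  iteration, and a free outcome-selection slope — which couples
  strongly with the imputations — is refreshed again after each
  imputation sweep.
* **Missing scores** are proposed from the exact Gaussian full
  conditional implied by the score regressions and accepted against
  the logistic selection factors. Under MAR constraints the acceptance
  ratio is identically 1, so imputation is exact Gibbs there.

Coefficients have uniform priors on [−50, 50] by default (configurable;
wide enough that the bound never binds at the likelihood scale of this
model), replaced by normal priors where elicited beliefs are supplied.
Coefficients in `spec$fixed` are point masses: they appear in every
draw at their fixed value. Chains are initialized from least-squares
and one-step GLM fits on mean-imputed data with chain-specific jitter;
a single integer seed fans out into independent per-chain streams, and
identical seeds reproduce draws exactly.

Convergence is assessed by the Brooks–Gelman corrected potential scale
reduction factor (`gelman_rubin()`, flag threshold 1.05, validated
against `coda::gelman.diag` to 1e-8); exceedances raise a warning and
are recorded in the fit, never silently dropped. Attempting the fully
unconstrained selection model (all sensitivity arcs free with flat
priors) triggers an explicit warning: that model is known to be so
poorly identified that its posterior is practically unusable, and the
package does not offer it as a supported analysis.

The reported quantities are the treatment effect $\delta_{T,Y_1}$
(`treatment_effect_summary()`, equal-tailed 2.5/97.5% intervals) and
$\Delta(Y_1, \text{arm})$, the posterior mean of the imputed missing
final scores minus the observed mean in that arm
(`delta_missing_minus_observed()`) — a direct, score-scale reading of
what the assumed mechanism implies about the missing data.

## The synthetic-data generator

`simulate_trial()` draws a complete trial along the same causal
ordering with known parameters and then deletes values whose indicator
is zero, returning both the released dataset and the full truth
record. Defaults (`quatro_sim_params()`) are calibrated by moment
matching to the published margins of the motivating four-centre
adherence-therapy trial in schizophrenia (409 participants): baseline
mean 39 / pooled SD 11, final mean 41 / SD 12, a small harmful effect
(−0.4 points), 37/18/5 of 409 in the baseline-only / final-only /
neither patterns, proxy mean 20 / SD 6 with complete-case correlation
0.31 and 379 proxies recorded, and contact-attempt bands of about 42%
single-attempt and 7% beyond three. Missingness in the default
parameter set is MAR (all score-selection coefficients zero): the
calibration targets are marginal summaries only, and the published
tables cannot identify an MNAR truth.

Choices the published margins do not determine, made once here:

* **Interviewers' stopping rule.** Attempt bands count non-responders
  too, so non-responders cannot all have nine failed attempts. The
  generator draws a give-up decision after each failure
  (`giveup_hazard`, default (0.02, 0.28, 0.17, 0.25, ...)), calibrated
  together with the per-attempt intercepts to the published band
  proportions. The allocation of non-responders within bands is a free
  choice, likewise in the deterministic `quatro_margins_fixture()`.
* **Attempt type** is Bernoulli(0.7) with a +0.8 log-odds effect of a
  verbal agreement on success — a realistic magnitude the margins do
  not pin down.
* **Expert simulation** (`simulate_experts()`) uses one `dispersion`
  parameter for both the between-expert spread of belief centres and
  each expert's own uncertainty, so dispersion 0 degenerates to all
  weight on the category containing the truth.

The generator deliberately matches the analysis model's distributional
families (normal scores, logistic selection), so parameter recovery is
a clean check of the sampler rather than of robustness. What passing
tests therefore do *not* show: behaviour under model misspecification
(non-normal scores, non-logistic selection, centre-by-covariate
interactions), under real interviewer behaviour, or for the actual
trial's unavailable individual-level data.

## Problem sizes and numerical choices

The test suite and examples run at desk scale, chosen as the smallest
sizes at which each property is comfortably signal-dominated: MAR
recovery at n = 800 with 4 chains of 2,500 kept draws; the sensitivity
grid at n = 600; attempts identifiability at n = 2,000 (the slope
posterior SD is then ~0.06 against a true 0.5); the proxy failure mode
at n = 1,200; a 100-replicate coverage study at n = 120 with short
chains. Conventional full-scale runs (4 × 25,000/25,000) are available
via `mcmc_config(paper_scale = TRUE)`. Equality tolerances in tests
are exact for arithmetic identities (1e-10 or tighter), and
Monte-Carlo-error-sized for posterior comparisons.

Degenerate inputs are handled explicitly: empty datasets produce
all-zero descriptive tables; empty grids produce empty reports; a
single chain errors in `gelman_rubin()`; non-positive variances, SDs
and anchor denominators error early with named messages; constant
(fixed) parameters report `NA` scale-reduction rather than 0/0.

## Limitations

* Identification of $\delta_{Y_1,R_1}$ via proxies or attempts rests
  on assumptions (conditional independence; slope homogeneity across
  attempts) that the data can at best partially test.
* The random-walk Metropolis blocks are adequate at trial scale but
  would need gradient-based kernels for much larger covariate sets.
* The attempts model follows the published covariate set; the
  interaction-screening step that produced it is not re-run, since on
  synthetic data it could select a different set and silently change
  the estimand.
* Proxy models are main-effects-only by design.
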