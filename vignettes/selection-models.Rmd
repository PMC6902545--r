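---
title: "Correcting endogenous outcome missingness with selection models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting endogenous outcome missingness with selection models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In many field settings a health outcome is recorded only for a non-random
subset of subjects. Birth weight is the canonical example: it is measured
only when a mother delivers at a facility with working scales, and the
same unmeasured traits (health knowledge, preventive effort) that make a
facility delivery more likely also predict the infant's weight. Dropping
the missing rows (complete-case analysis, CCA) then conditions on a
collider, and no imputation model built from *observed* covariates can
restore what was never observed: the missingness carries information about
the outcome itself. This package implements the classical sample-selection
(type-2 tobit) machinery for that situation, together with the comparison
methods an applied analyst would otherwise reach for, and a Monte-Carlo
harness that measures what each method delivers.

## Model

Two latent equations with jointly normal errors:

$$y_i^* = x_i'\beta + \mu_i, \qquad s_i^* = z_i'\gamma + \nu_i,$$
$$(\mu_i, \nu_i) \sim N\!\left(0, \begin{pmatrix} \sigma^2 & \rho\sigma \\
\rho\sigma & 1 \end{pmatrix}\right),$$

with $y_i$ observed iff $s_i^* > 0$. The outcome covariates $x$ are a
subset of the selection covariates $z$; at least one element of $z$
excluded from $x$ (here: distance to the nearest facility) is strongly
recommended, since otherwise identification rests on the nonlinearity of
the inverse Mills ratio alone — `model_data()` warns in that case and the
two-step fit always records a condition-number diagnostic on the augmented
design.

Conditional on selection,
$E[y \mid x, s = 1] = x'\beta + \rho\sigma\,\lambda(z'\gamma)$ with
$\lambda(u) = \phi(u)/\Phi(u)$ the inverse Mills ratio. Two estimators are
provided:

* **Two-step** (`heckman_two_step()`): probit of $s$ on $Z$, then OLS of
  $y$ on $[X, \hat\lambda]$ over the selected rows. $\hat\sigma^2$ is
  recovered as $\mathrm{RSS}/n_1 + \overline{\delta}\,\hat\beta_\lambda^2$
  with $\delta_i = \hat\lambda_i(\hat\lambda_i + z_i'\hat\gamma)$, and
  $\hat\rho = \hat\beta_\lambda/\hat\sigma$, clamped to $[-0.99, 0.99]$
  with a warning so $\hat\sigma$ stays interpretable. The reported step-2
  standard errors are the unadjusted OLS ones — they ignore the estimation
  error in $\hat\gamma$ — so the FIML standard errors are the primary
  inferential output and the two-step fit serves mainly as a starting
  value and a fast diagnostic.
* **FIML** (`heckman_fiml()`): joint maximum likelihood, with unselected
  rows contributing $\log\Phi(-z'\gamma)$ and selected rows the normal
  density of $y$ plus
  $\log\Phi\{(z'\gamma + (\rho/\sigma)(y - x'\beta))/\sqrt{1-\rho^2}\}$.

For a binary outcome (low birth weight), `heckman_probit_fiml()` replaces
the outcome equation by a probit and evaluates the resulting bivariate
normal orthant probabilities with an R port of Genz's refinement of the
Drezner–Wesolowsky algorithm (absolute accuracy about $10^{-15}$,
cross-checked against two-dimensional quadrature in the test suite). Its
average marginal effect for a binary covariate is averaged over the
covariate profiles of *all* rows, selected or not, because the estimand is
the population probability of the outcome.

`test_rho_zero()` tests the exogeneity hypothesis $\rho = 0$. The primary
statistic is a likelihood ratio: under the restriction the likelihood
factorises into a selection probit plus a normal regression on the
selected rows, both of which have standard ML solutions, so the restricted
maximum is computed in closed form rather than by a second numerical
optimisation. A Wald test on $\mathrm{atanh}\,\hat\rho$ is reported
alongside, and the result degrades to Wald-only if the restricted pieces
cannot be fitted.

## Comparison methods

* `mean_impute()` — every missing outcome replaced by the overall observed
  mean (deflates the outcome variance by construction).
* `pida_impute()` — pattern imputation with delta adjustment: a
  deterministic fill at the observed mean shifted by $\delta$ times the
  observed SD ($\delta = \pm 0.5$ are the standard sensitivity scenarios),
  or at the subject's own treatment-group observed mean. No noise is
  added; these are sensitivity analyses, not estimators of a single truth.
* `mice_impute()` — Bayesian normal linear-regression imputation: residual
  variance drawn from its scaled inverse-$\chi^2$ posterior, coefficients
  from their conditional normal posterior, missing outcomes filled with a
  linear prediction plus noise. With a single incomplete variable the
  chained-equations cycle has exactly one step, so this is the complete
  MICE procedure for this data pattern. Predictive-mean matching is a
  documented switch point if it is ever added; the analysis default is
  `m = 150` imputations, while the Monte-Carlo harness defaults to
  `m = 25` to keep replicated runs affordable.
* `rubin_pool()` — standard combining rules; total variance
  $W + (1 + 1/m)B$ and the usual large-sample degrees of freedom.

## The synthetic cohort generator

`generate_complete()` draws, for each of $n$ births:

| quantity | distribution | default |
|---|---|---|
| treatment (supplementation) | Bernoulli($p_\mathrm{treat}$) | $p_\mathrm{treat} = 0.5$ |
| distance to facility (km) | Uniform$(0, d_{\max})$ | $d_{\max} = 10$ |
| health knowledge (latent) | $N(0, 1)$ | — |
| birth weight (g) | $3000 + 50\,\mathrm{treat} + 100\,\mathrm{knowledge} + e$ | $e \sim N(0, \sqrt{500^2 - 100^2})$ |

The nominal mean 3000 g and SD 500 g describe untreated births; the
idiosyncratic SD is set to $\sqrt{500^2 - 100^2} \approx 489.9$ g so that
the *total* SD including the knowledge component is exactly 500 g — the
only way to keep both printed moments simultaneously true once a latent
confounder carries part of the variance. Treatment is assigned at random
with probability 0.5: no supplementation rate is dictated by the study
design, and 0.5 maximises the precision of the treatment contrast. The
bounded uniform distance keeps selection probabilities away from 0 and 1
and gives the exclusion restriction genuine variation.

Missingness mechanisms:

* `apply_mar()` — i.i.d. Bernoulli removal at rate 0.4 (an exact-fraction
  subsample would be statistically equivalent at $n = 10{,}000$ and is not
  used).
* `apply_mnar()` — latent propensity
  $s^* = \alpha_0 + \alpha_t\,\mathrm{treat} + \alpha_k\,\mathrm{knowledge}
  - \alpha_d\,\mathrm{distance} + \varepsilon$, $\varepsilon \sim N(0,1)$,
  observed iff $s^* > 0$. Defaults $\alpha_k = 1$, $\alpha_d = 0.25$/km,
  $\alpha_t = 0.5$.

Two generator choices deserve emphasis. First, the selection noise
$\varepsilon$ is independent of the outcome noise $e$, so *all*
correlation between the equations flows through knowledge; the composite
errors are then exactly bivariate normal and the selection model is
correctly specified — the experiment measures the estimators under their
own assumptions, not their robustness to misspecification. The implied
error correlation is
$\rho = \alpha_k \cdot 100 / (500\sqrt{1 + \alpha_k^2}) \approx 0.14$.
Second, the selection equation loads on treatment ($\alpha_t > 0$). The
model's premise is that every outcome predictor also predicts selection
($x \subseteq z$), and supplementation uptake and facility delivery share
behavioural drivers; without this loading, selection would be independent
of the randomised treatment and the complete-case coefficient would be
unbiased, leaving nothing for the correction to correct. With it, treated
subjects clear a lower selection threshold, so the observed treated group
has a less favourable knowledge mix than the observed untreated group and
the complete-case estimate is pulled toward zero. The value 0.5 is a
strong-but-plausible probit coefficient for a behavioural covariate of
this kind. A side effect worth knowing when reading the pattern-imputation
sensitivity results: because treated subjects are over-observed, a
*constant* fill value moves the untreated group mean more than the treated
one, so the $-0.5$ SD scenario sits *above* the group-mean scenario and
the $+0.5$ SD scenario below it.

`calibrate_intercept()` sets $\alpha_0$ by root-finding so that
$P(s^* > 0)$, computed as
$E_{t,d}[\Phi\{(\alpha_0 + \alpha_t t - \alpha_d d)/\sqrt{1+\alpha_k^2}\}]$
by quadrature over the distance distribution and the treatment mixture,
equals the target observed fraction (default 0.60, matching the 40%
missingness of the MAR scenario so the scenarios are comparable).

Randomness contract: one master seed; sub-streams for treatment, distance,
knowledge, outcome noise, selection noise, the MAR mask and the imputation
draws are derived deterministically from it, so toggling one component
never perturbs the others, and identical seeds give bit-identical cohorts.
Each Monte-Carlo replicate redraws covariates as well as noise — whether a
replicated design should hold covariates fixed is a genuinely open choice;
redrawing everything measures the unconditional sampling distribution.

What the generator does *not* emulate: covariate-dependent treatment
uptake, village-level clustering, non-normal or heteroskedastic outcome
errors, missingness in covariates, and any covariate structure beyond the
three simulation variables. Passing tests therefore certify the estimators
under correctly specified joint normality, not their behaviour on real
surveillance data.

## Numerical choices

* Probit: Newton iterations with the analytic score and observed-information
  Hessian, step-halving, convergence at max |score| $< 10^{-8}$, at most
  100 iterations. Perfect separation is detected (essentially perfect
  classification of every row) and reported as an error naming the
  separating column, since the ML estimate then does not exist.
* FIML: $\rho$ is estimated through $\mathrm{atanh}$ and $\sigma$ through
  $\log$, making the search space unconstrained; BFGS with analytic
  gradients and parameter scaling is followed by a few damped Newton
  steps, because BFGS alone can stall in the nearly flat
  outcome-coefficient directions (the test suite verifies agreement with a
  brute-force maximisation to $10^{-3}$ per parameter). Standard errors
  come from the observed information in the transformed space,
  delta-method back-transformed; $|\hat\rho| > 0.995$ is flagged as a
  boundary fit.
* The inverse Mills ratio is computed as
  $\exp\{\log\phi(u) - \log\Phi(u)\}$, which stays accurate to the end of
  the double-precision range (checked against the asymptotic expansion
  down to $u = -37$).
* Starting values: FIML starts from the two-step fit, falling back to
  (OLS-on-selected, probit, $\rho = 0$) when the two-step fit fails.
* Confidence intervals are Wald intervals throughout; imputation pooling
  uses a $t$ interval with the Rubin degrees of freedom.

## Monte-Carlo harness and problem sizes

`run_mc()` runs scenario × estimator × replicate grids with per-replicate
seeds derived deterministically from the base seed (any subset of
replicates is reproducible in isolation, and execution order cannot affect
results). Summaries report mean, SD, bias, RMSE, 95% CI coverage and the
converged-replicate count; an estimator failing more than 20% of
replicates aborts the run. The package's standard experiment size is 200
replicates of $n = 10{,}000$ — large enough that the Monte-Carlo standard
error of a mean estimate is below 1.1 g for every estimator — with the
full 1000-replicate version available by setting `reps` in
`mc_scenario()`. The `mice` estimator uses `m = 25` inside replicated
runs. `summarize_panels()` draws the estimate histograms per
estimator-scenario cell with a reference line at the true effect and
reports the variance comparison between the corrected and uncorrected
estimators: the selection correction pays for unbiasedness with visibly
larger sampling variance, since $\beta$ and $\rho\sigma\lambda$ compete
for the same variation.

## Known limitations

* The endogeneity LR test has modest power at the default error
  correlation ($\rho \approx 0.14$): a single cohort of 10,000 births
  rejects at the 1% level in roughly three quarters of draws. The test
  suite therefore checks its behaviour at replicate level (median p-value
  under endogenous selection; false-rejection rate under the null).
* Two-step standard errors are unadjusted (see above).
* No clustered or panel selection structures, no non-normal error
  distributions, no covariate missingness, no multilevel outcome models.
* `heckman_probit_fiml()` uses numeric derivatives; it is accurate but
  slower than the continuous-outcome FIML, and reports no delta-method
  standard error for its marginal effect.
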