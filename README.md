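# heckmiss

Heckman-type selection models for outcomes that are missing **not** at
random, with the comparison methods an applied analyst would otherwise use
and a Monte-Carlo harness to measure what each delivers.

## The problem

Birth weight in low-income settings is recorded only when a mother delivers
at a facility that weighs newborns. The unmeasured traits that make a
facility delivery more likely — health knowledge, preventive effort — also
predict the infant's weight, so restricting an analysis to complete cases
conditions on the outcome's own determinants and biases the estimated
effect of an exposure such as antenatal iron/folic-acid supplementation.
Imputation from observed covariates cannot repair this: the missingness
itself carries information about the outcome.

## The model

Two latent equations with jointly normal errors,

```
y* = x'β + μ,   s* = z'γ + ν,   (μ, ν) ~ N(0, [[σ², ρσ], [ρσ, 1]]),
```

where `y` is observed iff `s* > 0` and the outcome covariates `x` are a
subset of the selection covariates `z`. Conditional on selection,
`E[y | x, s=1] = x'β + ρσ·λ(z'γ)` with `λ(u) = φ(u)/Φ(u)` the inverse
Mills ratio. The package provides:

* `heckman_two_step()` — probit of `s` on `Z`, then OLS of `y` on
  `[X, λ̂]` over the selected rows;
* `heckman_fiml()` — full-information maximum likelihood for the joint
  model (the primary inferential fit);
* `heckman_probit_fiml()` — the bivariate-probit-with-selection variant
  for binary outcomes such as low birth weight;
* `test_rho_zero()` — likelihood-ratio (and Wald) test of the exogeneity
  hypothesis ρ = 0;
* comparison methods: complete-case OLS (`fit_ols`), `mean_impute()`,
  `pida_impute()` (pattern imputation with ±0.5 SD delta adjustment or
  group means), `mice_impute()` + `rubin_pool()`;
* a synthetic birth-cohort generator (`sim_params`, `generate_complete`,
  `apply_mar`, `apply_mnar`) with a latent health-knowledge confounder,
  and a Monte-Carlo harness (`mc_scenario`, `run_mc`, `summarize_panels`).

## Worked example

Simulate one cohort of 10,000 births in which supplementation raises birth
weight by 50 g, knowledge raises it by 100 g/SD, and the outcome is
observed for ~60% of births with observation probability increasing in
supplementation and knowledge and decreasing in distance to facility:

```r
library(heckmiss)

params <- preset_params("paper-mnar", seed = 42)
cohort <- apply_mnar(generate_complete(params, seed = 42), params, seed = 42)
md <- model_data(cohort, outcome = "bw_obs", x_cols = "treat",
                 z_cols = c("treat", "distance"))

fit_ols(md, use_selected_only = TRUE)$coef[["treat"]]  # complete-case OLS
#> [1] 23.09659

fit <- heckman_fiml(md)
fit
#> Heckman selection model (FIML)
#> Outcome equation:
#>              estimate      se
#> (Intercept) 3012.3140 18.0966
#> treat         32.5183 13.4664
#> Selection equation:
#>             estimate     se
#> (Intercept)   1.0236 0.0313
#> treat         0.4023 0.0270
#> distance     -0.1828 0.0049
#> rho = 0.1084, sigma = 495.582, lambda = rho*sigma = 53.728
#> log-likelihood = -52144.384
```

On this draw the complete-case estimate (23.1 g) is pulled well below the
true 50 g; the selection model moves it back toward the truth (32.5 g,
within one standard error of 50) and recovers the positive error
correlation (`rho` > 0, i.e. the same unobservables raise both birth
weight and the chance of observing it) along with the selection equation's
treatment and distance loadings. Single draws are noisy — the Monte-Carlo
distribution below is the real comparison. At the default error
correlation (ρ ≈ 0.14) a single cohort also does not always reject ρ = 0
at the 1% level; see the methods vignette for the power analysis.

Replicating the whole experiment (this is the 200-replicate study-scale
run; it takes a few minutes):

```r
res <- run_mc(mc_scenario("mnar", estimators = c("cca", "heckman_fiml"),
                          reps = 200, base_seed = 101))
res
#> Monte-Carlo study: scenario 'mnar', 200 replicates, n = 10000
#>  scenario    estimator mean_est sd_est   bias  rmse ci_coverage n_converged
#>      mnar          cca    38.93  12.41 -11.07 16.60        0.89         200
#>      mnar heckman_fiml    50.09  13.22   0.09 13.19        0.94         200
```

`bias` is the mean deviation from the true 50 g effect: complete-case OLS
is biased toward zero by an amount many Monte-Carlo standard errors wide,
while the FIML mean is statistically indistinguishable from 50 g at the
cost of a larger sampling SD.

A command-line wrapper covering `simulate`, `fit` and `mc` is installed at
`inst/scripts/heckmiss`:

```sh
Rscript inst/scripts/heckmiss simulate --preset paper-mnar --seed 1 --out cohort.csv
Rscript inst/scripts/heckmiss fit --in cohort.csv --method heckman_fiml --out params.csv
```

Every run writes a JSON manifest (full configuration, seed, package
version) next to its outputs.

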