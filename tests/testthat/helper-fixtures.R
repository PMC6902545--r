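# Shared fixtures: all inputs are generated in code at test time.

# Fixed seed for every acceptance-scale computation in the suite.
ACC_SEED <- 101L

# Cohort -> (y, X, s, Z) bundle with the simulation's standard design.
cohort_md <- function(cohort, outcome = "bw_obs") {
  model_data(cohort, outcome = outcome, x_cols = "treat",
             z_cols = c("treat", "distance"))
}

mnar_md <- function(n = 10000L, seed = 1L, ...) {
  p <- calibrate_intercept(sim_params(n = n, seed = seed, ...))
  cohort_md(apply_mnar(generate_complete(p, seed = seed), p, seed = seed))
}

# Memoised Monte-Carlo runs shared by the acceptance tests (200 replicates
# at the full n = 10,000 study scale; built once on first use).
.acc_cache <- new.env(parent = emptyenv())

acc_mc <- function(name) {
  if (!is.null(.acc_cache[[name]])) return(.acc_cache[[name]])
  scen <- switch(name,
    complete = mc_scenario("complete", estimators = "ols_full",
                           reps = 200L, base_seed = ACC_SEED),
    mar = mc_scenario("mar", estimators = c("cca", "mice"),
                      reps = 200L, base_seed = ACC_SEED, mice_m = 25L),
    mnar = mc_scenario("mnar",
                       estimators = c("cca", "mice", "heckman_fiml"),
                       reps = 200L, base_seed = ACC_SEED, mice_m = 25L))
  .acc_cache[[name]] <- run_mc(scen)
  .acc_cache[[name]]
}

acc_row <- function(name, estimator) {
  s <- acc_mc(name)$summary
  s[s$estimator == estimator, , drop = FALSE]
}

# Deterministic per-replicate seeds for test-local simulation loops.
.rep_seed_local <- function(base, r)
  as.integer((as.numeric(base) * 1013 + r * 7919) %% 2147483629)

# Independent selection-model log-likelihood, written directly from the
# density formula, for brute-force oracle maximisation in tests.
oracle_sel_negll <- function(th, y, X, s, Z) {
  p <- ncol(X); k <- ncol(Z)
  beta <- th[seq_len(p)]; gamma <- th[p + seq_len(k)]
  rho <- tanh(th[p + k + 1]); sigma <- exp(th[p + k + 2])
  zg <- drop(Z %*% gamma)
  sel <- s == 1
  e <- y[sel] - drop(X[sel, , drop = FALSE] %*% beta)
  ll <- sum(pnorm(-zg[!sel], log.p = TRUE)) +
    sum(dnorm(e / sigma, log = TRUE) - log(sigma) +
          pnorm((zg[sel] + rho * e / sigma) / sqrt(1 - rho^2),
                log.p = TRUE))
  -ll
}
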