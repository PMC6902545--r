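test_that("bivariate normal CDF matches quadrature to full precision", {
  expect_equal(pbinorm(0, 0, 0), 0.25, tolerance = 1e-14)
  expect_equal(pbinorm(0, 0, 0.5), 0.25 + asin(0.5) / (2 * pi),
               tolerance = 1e-12)
  num2d <- function(x, y, r)
    integrate(function(u) sapply(u, function(ui)
      dnorm(ui) * pnorm((y - r * ui) / sqrt(1 - r^2))),
      -40, x, rel.tol = 1e-13)$value
  pts <- list(c(0.5, -1.2), c(-2, 1), c(1.5, 1.4), c(-0.3, 0.3))
  for (r in c(-0.999, -0.95, -0.6, -0.2, 0, 0.3, 0.8, 0.93, 0.999))
    for (hk in pts)
      expect_equal(pbinorm(hk[1], hk[2], r), num2d(hk[1], hk[2], r),
                   tolerance = 1e-8)
  # degenerate correlations collapse to the univariate forms
  expect_equal(pbinorm(0.7, 1.3, 1), pnorm(0.7), tolerance = 1e-14)
  expect_equal(pbinorm(0.7, -0.2, -1), pnorm(0.7) + pnorm(-0.2) - 1,
               tolerance = 1e-14)
})

test_that("selection independent of the outcome reduces to complete-case OLS", {
  md <- mnar_md(n = 10000L, seed = 17L, sel_alpha_k = 0)
  cca <- fit_ols(md, use_selected_only = TRUE)
  ts <- suppressWarnings(heckman_two_step(md))
  fi <- suppressWarnings(heckman_fiml(md))
  expect_lt(abs(ts$lambda_coef), 2 * ts$se[["lambda"]])
  expect_lt(abs(ts$beta[["treat"]] - cca$coef[["treat"]]),
            2 * cca$se[["treat"]])
  expect_lt(abs(fi$beta[["treat"]] - ts$beta[["treat"]]),
            fi$se[["beta:treat"]])
  expect_lt(abs(fi$beta[["treat"]] - cca$coef[["treat"]]),
            fi$se[["beta:treat"]])
  expect_lt(abs(fi$rho), 3 * fi$se[["rho"]])
})

test_that("endogenous selection is corrected and lambda carries its sign", {
  md <- mnar_md(n = 10000L, seed = 42L)
  cca <- fit_ols(md, use_selected_only = TRUE)
  ts <- heckman_two_step(md)
  fi <- heckman_fiml(md)
  expect_true(fi$converged)
  expect_lt(abs(fi$beta[["treat"]] - 50), 3 * fi$se[["beta:treat"]])
  expect_lt(abs(ts$beta[["treat"]] - 50), 3 * fi$se[["beta:treat"]])
  # complete-case estimate on the same draw is pulled toward zero
  expect_lt(cca$coef[["treat"]], fi$beta[["treat"]])
  # positive selection on the outcome: cov(mu, nu) = 100 * sel_alpha_k > 0
  expect_gt(ts$lambda_coef, 0)
  expect_gt(fi$rho, 0)
  # internal consistency of the reported parameterisation
  expect_equal(fi$lambda_coef, fi$rho * fi$sigma, tolerance = 1e-6)
  expect_equal(ts$lambda_coef, ts$rho * ts$sigma, tolerance = 1e-6)
})

test_that("FIML attains at least the likelihood of its starting values", {
  for (seed in c(2L, 3L, 4L)) {
    md <- mnar_md(n = 2000L, seed = seed)
    ts <- suppressWarnings(heckman_two_step(md))
    fi <- suppressWarnings(heckman_fiml(md))
    expect_gte(fi$loglik, ts$loglik - 1e-8)
  }
})

test_that("two-step and FIML agree within sampling error per replicate", {
  for (seed in c(5L, 6L)) {
    md <- mnar_md(n = 5000L, seed = seed)
    ts <- suppressWarnings(heckman_two_step(md))
    fi <- suppressWarnings(heckman_fiml(md))
    pooled <- sqrt(ts$se[["beta:treat"]]^2 + fi$se[["beta:treat"]]^2)
    expect_lt(abs(ts$beta[["treat"]] - fi$beta[["treat"]]), 3 * pooled)
  }
})

test_that("FIML matches a brute-force likelihood maximisation", {
  md <- mnar_md(n = 200L, seed = 5L)
  fi <- suppressWarnings(heckman_fiml(md))
  th_pkg <- c(fi$beta, fi$gamma, atanh(fi$rho), log(fi$sigma))

  # independent start: lm + glm, rho = 0
  sel <- md$s == 1
  lm0 <- lm(md$y[sel] ~ md$X[sel, -1])
  gl0 <- glm(md$s ~ md$Z[, -1], family = binomial("probit"))
  start <- c(coef(lm0), coef(gl0), 0, log(summary(lm0)$sigma))
  f <- function(th) oracle_sel_negll(th, md$y, md$X, md$s, md$Z)
  o <- optim(start, f, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-15,
                            parscale = c(1000, 50, 1, 1, 1, 0.5, 0.5)))
  o <- optim(o$par, f, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-15,
                            parscale = c(1000, 50, 1, 1, 1, 0.5, 0.5)))
  o <- optim(o$par, f, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(th_pkg - o$par) / (1 + abs(o$par))), 1e-3)
  expect_equal(fi$loglik, -o$value, tolerance = 1e-7)
})

test_that("likelihood-ratio test for rho = 0 is coherent", {
  md <- mnar_md(n = 4000L, seed = 23L)
  fi <- suppressWarnings(heckman_fiml(md))
  tr <- test_rho_zero(fi, md)
  expect_identical(tr$method, "LR")
  expect_gte(tr$statistic, 0)
  expect_true(tr$p_value >= 0 && tr$p_value <= 1)
  expect_equal(tr$statistic,
               2 * (tr$loglik_full - tr$loglik_restricted),
               tolerance = 1e-9)
  # Wald companion uses the atanh(rho) scale
  expect_equal(tr$wald_statistic, atanh(fi$rho) / fi$se_atanh_rho,
               tolerance = 1e-9)
  # a two-step fit is refitted by FIML internally
  ts <- suppressWarnings(heckman_two_step(md))
  tr2 <- test_rho_zero(ts, md)
  expect_equal(tr2$statistic, tr$statistic, tolerance = 1e-4)
})

test_that("binary-outcome selection model nests the plain probit at rho = 0", {
  p <- sim_params(n = 4000L, seed = 11L)
  pc <- calibrate_intercept(p)
  cm <- apply_mnar(generate_complete(p, seed = 11L), pc, seed = 11L)
  cm$lbw <- ifelse(cm$selected == 1L, as.integer(cm$bw_true < 2500),
                   NA_integer_)
  md <- model_data(cm, outcome = "lbw", x_cols = "treat",
                   z_cols = c("treat", "distance"))
  f0 <- heckman_probit_fiml(md, fix_rho = 0)
  plain <- fit_probit(md$y[md$s == 1], md$X[md$s == 1, , drop = FALSE])
  expect_lt(max(abs(f0$beta - plain$coef)), 1e-4)

  # free-rho fit: protective treatment lowers P(low birth weight)
  f1 <- heckman_probit_fiml(md, margin_var = "treat")
  expect_true(f1$converged)
  expect_lt(f1$margin$ame, 0)
  expect_error(heckman_probit_fiml(cohort_md(cm), margin_var = "treat"),
               "binary")
})
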