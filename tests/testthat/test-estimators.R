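test_that("OLS reproduces an exact fit and the normal-equations solve", {
  df <- data.frame(y = c(2, 4, 6), x = 1:3, w = c(0, 1, 0))
  md <- model_data(df, outcome = "y", x_cols = "x", z_cols = c("x", "w"))
  fit <- fit_ols(md)
  expect_equal(unname(fit$coef[c("(Intercept)", "x")]), c(0, 2),
               tolerance = 1e-12)
  expect_lt(sum(fit$residuals^2), 1e-20)

  set.seed(31)
  X <- cbind("(Intercept)" = 1, a = runif(6), b = rnorm(6))
  y <- rnorm(6)
  md2 <- list(y = y, X = X, s = rep(1L, 6), Z = X)
  class(md2) <- "model_data"
  brute <- drop(solve(t(X) %*% X, t(X) %*% y))
  expect_equal(unname(fit_ols(md2)$coef), unname(brute), tolerance = 1e-10)
})

test_that("OLS on a complete cohort recovers the treatment effect", {
  p <- sim_params(seed = 2L)
  md <- cohort_md(generate_complete(p), outcome = "bw_true")
  fit <- fit_ols(md, use_selected_only = FALSE)
  expect_lt(abs(fit$coef[["treat"]] - 50), 3 * fit$se[["treat"]])
})

test_that("OLS residuals are orthogonal to the design", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 80
    X <- cbind("(Intercept)" = 1, a = scale(rnorm(n))[, 1],
               b = scale(runif(n))[, 1])
    md <- structure(list(y = rnorm(n), X = X, s = rep(1L, n), Z = X),
                    class = "model_data")
    fit <- fit_ols(md)
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8 * n)
  }
})

test_that("singular designs raise an error naming the collinear column", {
  df <- data.frame(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  md <- suppressWarnings(model_data(df, outcome = "y",
                                    x_cols = c("a", "b")))
  expect_error(fit_ols(md), "collinear.*b")
})

test_that("model_data enforces the design contracts", {
  df <- data.frame(y = c(1, NA, 3), x = 1:3, z = c(2, 1, 0),
                   s_ok = c(1L, 0L, 1L), s_bad = c(1L, 1L, 1L))
  md <- model_data(df, outcome = "y", x_cols = "x", z_cols = c("x", "z"))
  expect_identical(md$s, c(1L, 0L, 1L))
  expect_silent(model_data(df, outcome = "y", x_cols = "x",
                           select = "s_ok", z_cols = c("x", "z")))
  expect_error(model_data(df, outcome = "y", x_cols = "x",
                          select = "s_bad", z_cols = c("x", "z")),
               "contradicts outcome presence")
  expect_error(model_data(df, outcome = "y", x_cols = c("x", "q")),
               "not found")
  expect_error(model_data(df, outcome = "y", x_cols = c("x", "z"),
                          z_cols = "x"), "subset")
  expect_warning(model_data(df, outcome = "y", x_cols = "x", z_cols = "x"),
                 "excluded from the outcome")
  df$x[2] <- NA
  expect_error(model_data(df, outcome = "y", x_cols = "x",
                          z_cols = c("x", "z")), "covariate")
})

test_that("probit matches the inverse-normal-CDF closed forms", {
  Z1 <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit50 <- fit_probit(rep(c(1L, 0L), c(50, 50)), Z1)
  expect_equal(unname(fit50$coef), 0, tolerance = 1e-7)
  fit84 <- fit_probit(rep(c(1L, 0L), c(84, 16)), Z1)
  expect_equal(unname(fit84$coef), qnorm(0.84), tolerance = 1e-6)

  # saturated binary-covariate model reproduces the cell probabilities
  x <- rep(0:1, each = 100)
  s <- c(rep(c(1L, 0L), c(50, 50)), rep(c(1L, 0L), c(84, 16)))
  Z2 <- cbind("(Intercept)" = 1, x = x)
  fit2 <- fit_probit(s, Z2)
  expect_equal(unname(fit2$coef), c(0, qnorm(0.84)), tolerance = 1e-6)
  expect_true(fit2$converged)
})

test_that("probit agrees with an independent ML fit on simulated data", {
  set.seed(14)
  n <- 800
  z1 <- rnorm(n); z2 <- runif(n)
  s <- as.integer(runif(n) < pnorm(0.3 + 0.8 * z1 - 1.2 * z2))
  Z <- cbind("(Intercept)" = 1, z1 = z1, z2 = z2)
  fit <- fit_probit(s, Z)
  ref <- glm(s ~ z1 + z2, family = binomial("probit"))
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-9)
  # observed-information SEs vs glm's expected-information ones
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-2)

  # maximised log-likelihood dominates the zero coefficient vector
  expect_gt(fit$loglik, n * log(0.5))
})

test_that("probit rejects degenerate and separated responses", {
  Z <- cbind("(Intercept)" = 1, x = c(rep(0, 5), rep(1, 5)))
  expect_error(fit_probit(rep(1L, 10), Z), "degenerate")
  expect_error(fit_probit(c(rep(0L, 5), rep(1L, 5)), Z), "separation")
})

test_that("probit marginal effects match their oracles", {
  x <- rep(0:1, each = 100)
  s <- c(rep(c(1L, 0L), c(50, 50)), rep(c(1L, 0L), c(84, 16)))
  Z <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_probit(s, Z)
  m <- probit_margins(fit, Z, "x")
  expect_equal(m$ame, 0.34, tolerance = 1e-6)
  expect_identical(m$type, "discrete")
  expect_true(m$ame > -1 && m$ame < 1)
  expect_true(m$ci_low < m$ame && m$ame < m$ci_high)
  expect_error(probit_margins(fit, Z, "nope"), "unknown column")

  # a null coefficient gives a null effect
  fit0 <- fit
  fit0$coef["x"] <- 0
  expect_equal(probit_margins(fit0, Z, "x")$ame, 0)

  # continuous AME equals the finite-difference derivative of the mean
  # predicted probability under a uniform shift of the column
  set.seed(15)
  n <- 500
  zc <- rnorm(n)
  sc <- as.integer(runif(n) < pnorm(0.2 + 0.7 * zc))
  Zc <- cbind("(Intercept)" = 1, zc = zc)
  fc <- fit_probit(sc, Zc)
  mc <- probit_margins(fc, Zc, "zc")
  h <- 1e-5
  shift <- function(d) mean(pnorm(drop(cbind(1, zc + d) %*% fc$coef)))
  expect_equal(mc$ame, (shift(h) - shift(-h)) / (2 * h), tolerance = 1e-6)
})

test_that("inverse Mills ratio matches closed forms and is well behaved", {
  expect_equal(inverse_mills(0), dnorm(0) / 0.5, tolerance = 1e-12)
  u <- seq(-37, 37, by = 0.01)
  lam <- inverse_mills(u)
  expect_true(all(is.finite(lam)))
  expect_true(all(lam > 0))
  expect_true(all(lam > -u))
  expect_true(all(diff(lam) < 0))  # strictly decreasing

  # deep lower tail: asymptotic Mills-ratio expansion as the oracle
  t <- 37
  series <- t / (1 - 1 / t^2 + 3 / t^4 - 15 / t^6)
  expect_equal(inverse_mills(-37), series, tolerance = 1e-8)
  expect_lt(abs(inverse_mills(-37) - 37) / 37, 1e-3)
  expect_error(inverse_mills(Inf), "finite")
})
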