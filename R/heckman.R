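# Heckman sample-selection estimators for a continuous outcome:
# two-step (probit + inverse-Mills-augmented OLS) and full-information
# maximum likelihood, plus the likelihood-ratio test for endogenous
# selection (rho = 0).

.heckman_fit <- function(beta, gamma, rho, sigma, se, loglik, converged,
                         method, extra = list()) {
  out <- c(list(beta = beta, gamma = gamma, rho = rho, sigma = sigma,
                lambda_coef = rho * sigma, se = se, loglik = loglik,
                converged = converged, method = method), extra)
  class(out) <- "heckman_fit"
  out
}

#' @export
print.heckman_fit <- function(x, ...) {
  cat(sprintf("Heckman selection model (%s)\n",
              if (x$method == "two_step") "two-step" else "FIML"))
  cat("Outcome equation:\n")
  print(round(cbind(estimate = x$beta,
                    se = x$se[paste0("beta:", names(x$beta))]), 4))
  cat("Selection equation:\n")
  print(round(cbind(estimate = x$gamma,
                    se = x$se[paste0("gamma:", names(x$gamma))]), 4))
  cat(sprintf("rho = %.4f, sigma = %.3f, lambda = rho*sigma = %.3f\n",
              x$rho, x$sigma, x$lambda_coef))
  if (is.finite(x$loglik)) cat(sprintf("log-likelihood = %.3f\n", x$loglik))
  if (!x$converged) cat("WARNING: not converged\n")
  invisible(x)
}

# Selection-model log-likelihood at natural parameters (beta, gamma, rho,
# sigma). Unselected rows contribute log Phi(-z'gamma); selected rows the
# conditional normal density of y plus log Phi of the adjusted selection
# index.
.sel_loglik <- function(beta, gamma, rho, sigma, data) {
  s1 <- data$s == 1L
  zg <- drop(data$Z %*% gamma)
  ll0 <- stats::pnorm(-zg[!s1], log.p = TRUE)
  u <- (data$y[s1] - drop(data$X[s1, , drop = FALSE] %*% beta)) / sigma
  q <- (zg[s1] + rho * u) / sqrt(1 - rho^2)
  ll1 <- stats::dnorm(u, log = TRUE) - log(sigma) +
    stats::pnorm(q, log.p = TRUE)
  sum(ll0) + sum(ll1)
}

# theta = (beta, gamma, atanh(rho), log(sigma)); negative log-likelihood and
# analytic gradient in the transformed space.
.sel_negll <- function(theta, data, p, k) {
  beta <- theta[seq_len(p)]
  gamma <- theta[p + seq_len(k)]
  rho <- tanh(theta[p + k + 1])
  sigma <- exp(theta[p + k + 2])
  -.sel_loglik(beta, gamma, rho, sigma, data)
}

.sel_negll_grad <- function(theta, data, p, k) {
  beta <- theta[seq_len(p)]
  gamma <- theta[p + seq_len(k)]
  a <- theta[p + k + 1]; rho <- tanh(a)
  sigma <- exp(theta[p + k + 2])
  s1 <- data$s == 1L
  Z1 <- data$Z[s1, , drop = FALSE]; Z0 <- data$Z[!s1, , drop = FALSE]
  X1 <- data$X[s1, , drop = FALSE]
  zg1 <- drop(Z1 %*% gamma); zg0 <- drop(Z0 %*% gamma)
  r <- sqrt(1 - rho^2)
  u <- (data$y[s1] - drop(X1 %*% beta)) / sigma
  q <- (zg1 + rho * u) / r
  m <- inverse_mills(q)          # phi(q)/Phi(q)
  m0 <- inverse_mills(-zg0)
  g_beta <- drop(crossprod(X1, u / sigma - m * rho / (sigma * r)))
  g_gamma <- drop(crossprod(Z1, m / r)) - drop(crossprod(Z0, m0))
  g_a <- sum(m * (u * r + rho * q))          # already times d rho/d a
  g_t <- sum((u^2 - 1) - m * rho * u / r)    # times d sigma/d t = sigma
  -c(g_beta, g_gamma, g_a, g_t)
}

.named_se <- function(beta, gamma) {
  c(paste0("beta:", names(beta)), paste0("gamma:", names(gamma)),
    "rho", "sigma", "lambda")
}

#' Heckman two-step estimator
#'
#' Step 1: probit of the selection indicator on `Z`. Step 2: OLS of the
#' observed outcome on `X` augmented with the inverse Mills ratio
#' `lambda(z'gamma_hat)` over the selected rows. The residual SD and error
#' correlation are recovered from the step-2 residual variance and the
#' coefficient on the Mills ratio (`lambda_coef = rho * sigma`), with `rho`
#' clamped to [-0.99, 0.99].
#'
#' Step-2 standard errors are the unadjusted OLS ones: they ignore the
#' estimation error in `gamma_hat`, so FIML standard errors
#' ([heckman_fiml()]) are the primary inferential output. A condition-number
#' diagnostic on the augmented design `[X, lambda]` is always recorded in
#' `$diagnostics`; near-collinearity (no exclusion restriction and a
#' near-linear index) raises a warning, not an error.
#'
#' @param data A [model_data()] bundle with both selected and unselected rows.
#' @return A `heckman_fit` (method `"two_step"`); `$loglik` is the selection
#'   likelihood evaluated at the two-step parameter values.
#' @export
heckman_two_step <- function(data) {
  if (!any(data$s == 0L) || !any(data$s == 1L))
    stop("heckman_two_step: need both selected and unselected rows",
         call. = FALSE)
  step1 <- fit_probit(data$s, data$Z)
  zg <- drop(data$Z %*% step1$coef)
  s1 <- data$s == 1L
  lam <- inverse_mills(zg[s1])
  Xa <- cbind(data$X[s1, , drop = FALSE], lambda = lam)
  kappa_aug <- kappa(scale(Xa[, -1, drop = FALSE]), exact = TRUE)
  if (is.finite(kappa_aug) && kappa_aug > 1e6)
    warning("heckman_two_step: inverse Mills ratio nearly collinear with ",
            "the outcome design (condition number ",
            format(kappa_aug, digits = 3),
            "); estimates may be unstable without an exclusion restriction",
            call. = FALSE)
  qx <- qr(Xa)
  cf <- qr.coef(qx, data$y[s1])
  res <- data$y[s1] - drop(Xa %*% cf)
  n1 <- sum(s1)
  lambda_coef <- cf[["lambda"]]
  delta <- lam * (lam + zg[s1])
  sigma2 <- sum(res^2) / n1 + mean(delta) * lambda_coef^2
  sigma <- sqrt(sigma2)
  rho <- lambda_coef / sigma
  if (abs(rho) > 0.99) {
    warning("heckman_two_step: implied rho = ", format(rho, digits = 4),
            " outside [-0.99, 0.99]; clamped", call. = FALSE)
    rho <- sign(rho) * 0.99
  }
  # unadjusted OLS covariance for step 2 (documented caveat)
  XtX_inv <- chol2inv(qr.R(qx))
  s2_ols <- sum(res^2) / (n1 - ncol(Xa))
  se2 <- sqrt(diag(s2_ols * XtX_inv))
  beta <- cf[-length(cf)]
  se <- c(se2[-length(se2)], step1$se, NA_real_, NA_real_,
          se2[length(se2)])
  names(se) <- .named_se(beta, step1$coef)
  .heckman_fit(beta, step1$coef, rho, sigma, se,
               loglik = .sel_loglik(beta, step1$coef, rho, sigma, data),
               converged = step1$converged, method = "two_step",
               extra = list(diagnostics = list(condition_number = kappa_aug),
                            n_selected = n1, n_total = length(data$s)))
}

#' Heckman estimator by full-information maximum likelihood
#'
#' Jointly maximises the selection likelihood over the outcome coefficients,
#' selection coefficients, error correlation `rho` (parameterised through
#' `atanh`) and residual SD `sigma` (through `log`), by BFGS with analytic
#' gradients. Standard errors come from the observed information in the
#' transformed space, delta-method back-transformed.
#'
#' @param data A [model_data()] bundle with both selected and unselected rows.
#' @param init Optional `heckman_fit` supplying starting values; defaults to
#'   the two-step fit, falling back to (OLS on selected, probit, rho = 0).
#' @return A `heckman_fit` (method `"fiml"`).
#' @export
heckman_fiml <- function(data, init = NULL) {
  p <- ncol(data$X); k <- ncol(data$Z)
  if (is.null(init)) {
    init <- tryCatch(suppressWarnings(heckman_two_step(data)),
                     error = function(e) NULL)
  }
  if (is.null(init)) {
    ols <- fit_ols(data, use_selected_only = TRUE)
    prb <- fit_probit(data$s, data$Z)
    start <- c(ols$coef, prb$coef, 0, log(ols$sigma))
  } else {
    rho0 <- max(min(init$rho, 0.95), -0.95)
    start <- c(init$beta, init$gamma, atanh(rho0), log(init$sigma))
  }
  negll <- function(th) .sel_negll(th, data, p, k)
  negll_grad <- function(th) .sel_negll_grad(th, data, p, k)
  opt <- stats::optim(start, negll, negll_grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12,
                                     parscale = pmax(abs(start), 1)))
  theta <- opt$par
  # Newton polish: BFGS can stall in the nearly flat outcome-coefficient
  # directions; a few damped Newton steps reach the optimum to near
  # machine precision.
  for (it in seq_len(10)) {
    g <- negll_grad(theta)
    if (max(abs(g)) < 1e-8) break
    H <- tryCatch(stats::optimHess(theta, negll, negll_grad),
                  error = function(e) NULL)
    step <- if (!is.null(H)) tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- negll(theta)
    improved <- FALSE
    for (h in 0:20) {
      cand <- theta - step / 2^h
      fc <- negll(cand)
      if (is.finite(fc) && fc <= f0) { improved <- TRUE; break }
    }
    if (!improved) break
    theta <- cand
    opt$value <- fc
  }
  beta <- theta[seq_len(p)]; names(beta) <- colnames(data$X)
  gamma <- theta[p + seq_len(k)]; names(gamma) <- colnames(data$Z)
  a <- theta[p + k + 1]; t_log <- theta[p + k + 2]
  rho <- tanh(a); sigma <- exp(t_log)
  converged <- opt$convergence == 0L
  if (!converged) {
    gn <- max(abs(.sel_negll_grad(theta, data, p, k)))
    message("heckman_fiml: optimizer did not converge (max |gradient| = ",
            format(gn, digits = 3), ")")
  }
  if (abs(rho) > 0.995)
    warning("heckman_fiml: rho estimate at the boundary (|rho| = ",
            format(abs(rho), digits = 4), ")", call. = FALSE)
  H <- tryCatch(stats::optimHess(theta, negll, negll_grad),
                error = function(e) NULL)
  vc <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  np <- p + k + 2
  se <- rep(NA_real_, np + 1)
  vcov_nat <- NULL
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
    # delta method back to (rho, sigma, lambda = rho*sigma)
    J <- diag(np)
    J[p + k + 1, p + k + 1] <- 1 - rho^2   # d rho / d a
    J[p + k + 2, p + k + 2] <- sigma       # d sigma / d t
    vcov_nat <- J %*% vc %*% t(J)
    d_lambda <- numeric(np)
    d_lambda[p + k + 1] <- (1 - rho^2) * sigma
    d_lambda[p + k + 2] <- rho * sigma
    var_lambda <- drop(t(d_lambda) %*% vc %*% d_lambda)
    se <- c(sqrt(diag(vcov_nat)), sqrt(max(var_lambda, 0)))
  }
  names(se) <- .named_se(beta, gamma)
  .heckman_fit(beta, gamma, rho, sigma, se, loglik = -opt$value,
               converged = converged, method = "fiml",
               extra = list(vcov_trans = vc, se_atanh_rho =
                              if (!is.null(vc)) sqrt(vc[p + k + 1, p + k + 1])
                            else NA_real_,
                            n_selected = sum(data$s), n_total = length(data$s)))
}

#' Test the null hypothesis of no endogenous selection (rho = 0)
#'
#' Primary: likelihood-ratio test comparing the FIML fit to the restricted
#' model with `rho` fixed at 0, which factorises into a probit for selection
#' plus a normal regression on the selected rows (both with closed-form or
#' standard ML solutions). A Wald test on `atanh(rho)` is reported alongside;
#' if the restricted pieces fail to fit, the result degrades to Wald-only
#' with a message.
#'
#' @param fit A converged `heckman_fit`; a two-step fit is refitted by FIML
#'   first.
#' @param data The [model_data()] bundle the fit used.
#' @return List with `statistic`, `p_value`, `method` (`"LR"` or `"Wald"`),
#'   and the companion `wald_statistic`, `wald_p`.
#' @export
test_rho_zero <- function(fit, data) {
  if (!fit$converged)
    stop("test_rho_zero: fit did not converge", call. = FALSE)
  if (fit$method != "fiml") fit <- heckman_fiml(data, init = fit)
  z_w <- if (is.finite(fit$se_atanh_rho) && fit$se_atanh_rho > 0)
    atanh(fit$rho) / fit$se_atanh_rho else NA_real_
  wald_p <- if (is.finite(z_w)) 2 * stats::pnorm(-abs(z_w)) else NA_real_
  restricted <- tryCatch({
    prb <- fit_probit(data$s, data$Z)
    s1 <- data$s == 1L
    ols <- fit_ols(data, use_selected_only = TRUE)
    n1 <- sum(s1)
    sigma2_mle <- sum(ols$residuals^2) / n1
    ll_norm <- -n1 / 2 * (log(2 * pi) + log(sigma2_mle) + 1)
    prb$loglik + ll_norm
  }, error = function(e) NULL)
  if (is.null(restricted)) {
    message("test_rho_zero: restricted fit failed; reporting Wald test only")
    return(list(statistic = z_w^2, p_value = wald_p, method = "Wald",
                wald_statistic = z_w, wald_p = wald_p))
  }
  lr <- max(2 * (fit$loglik - restricted), 0)
  list(statistic = lr, p_value = stats::pchisq(lr, df = 1,
                                               lower.tail = FALSE),
       method = "LR", wald_statistic = z_w, wald_p = wald_p,
       loglik_full = fit$loglik, loglik_restricted = restricted)
}

#' Serialise a fit to a flat parameter CSV
#'
#' Writes one row per parameter: `parameter, estimate, se, ci_low, ci_high`.
#' Works for `heckman_fit` and `hm_fit` objects.
#'
#' @param fit A fit object.
#' @param path Output CSV path.
#' @return The parameter data frame, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  z <- stats::qnorm(0.975)
  tab <- if (inherits(fit, "heckman_fit")) {
    est <- c(stats::setNames(fit$beta, paste0("beta:", names(fit$beta))),
             stats::setNames(fit$gamma, paste0("gamma:", names(fit$gamma))),
             rho = fit$rho, sigma = fit$sigma, lambda = fit$lambda_coef)
    data.frame(parameter = names(est), estimate = unname(est),
               se = unname(fit$se[names(est)]),
               ci_low = unname(est - z * fit$se[names(est)]),
               ci_high = unname(est + z * fit$se[names(est)]))
  } else {
    data.frame(parameter = names(fit$coef), estimate = unname(fit$coef),
               se = unname(fit$se), ci_low = unname(fit$ci_low),
               ci_high = unname(fit$ci_high))
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
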