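# Binary-outcome selection model: a probit outcome equation and a probit
# selection equation with correlated latent errors (bivariate probit with
# sample selection), for outcomes such as low birth weight observed only
# when the birth was weighed.

# theta = (beta, gamma, atanh rho); negative log-likelihood.
# Contributions: s=0 -> log Phi(-z'gamma)
#                s=1, y=1 -> log Phi2( x'beta,  z'gamma;  rho)
#                s=1, y=0 -> log Phi2(-x'beta,  z'gamma; -rho)
.hp_negll <- function(theta, data, p, k, fixed_rho = NULL) {
  beta <- theta[seq_len(p)]
  gamma <- theta[p + seq_len(k)]
  rho <- if (is.null(fixed_rho)) tanh(theta[p + k + 1]) else fixed_rho
  s1 <- data$s == 1L
  zg <- drop(data$Z %*% gamma)
  xb <- drop(data$X[s1, , drop = FALSE] %*% beta)
  y1 <- data$y[s1] == 1
  pr <- numeric(sum(s1))
  pr[y1] <- pbinorm(xb[y1], zg[s1][y1], rho)
  pr[!y1] <- pbinorm(-xb[!y1], zg[s1][!y1], -rho)
  ll <- sum(stats::pnorm(-zg[!s1], log.p = TRUE)) +
    sum(log(pmax(pr, 1e-300)))
  -ll
}

#' Bivariate probit with sample selection
#'
#' Full-information maximum likelihood for a binary outcome observed only on
#' selected rows: probit outcome equation, probit selection equation, latent
#' error correlation `rho` (parameterised through `atanh`). The bivariate
#' normal probabilities use [pbinorm()]. Also reports the average marginal
#' effect of a named binary covariate on `P(y = 1)`, averaged over the
#' covariate profiles of *all* rows (selected and unselected), since the
#' estimand is the population probability.
#'
#' @param data A [model_data()] bundle whose outcome is 0/1 on selected rows.
#' @param margin_var Optional name of a binary outcome covariate whose
#'   average marginal effect is reported.
#' @param fix_rho Optional numeric: fix `rho` at this value instead of
#'   estimating it (e.g. `0` for the independence fit).
#' @return A `heckman_fit` (method `"probit_fiml"`, `sigma = 1`) with an
#'   extra `margin` element when `margin_var` is given.
#' @export
heckman_probit_fiml <- function(data, margin_var = NULL, fix_rho = NULL) {
  s1 <- data$s == 1L
  if (!any(s1) || !any(!s1))
    stop("heckman_probit_fiml: need both selected and unselected rows",
         call. = FALSE)
  yv <- data$y[s1]
  if (!all(yv %in% c(0, 1)))
    stop("heckman_probit_fiml: outcome must be binary 0/1 on selected rows",
         call. = FALSE)
  p <- ncol(data$X); k <- ncol(data$Z)
  # starting values: probit on selected, probit selection, rho = 0
  prb_y <- fit_probit(yv, data$X[s1, , drop = FALSE])
  prb_s <- fit_probit(data$s, data$Z)
  free_rho <- is.null(fix_rho)
  start <- c(prb_y$coef, prb_s$coef, if (free_rho) 0)
  negll <- function(th) .hp_negll(th, data, p, k, fixed_rho = fix_rho)
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  theta <- opt$par
  beta <- theta[seq_len(p)]; names(beta) <- colnames(data$X)
  gamma <- theta[p + seq_len(k)]; names(gamma) <- colnames(data$Z)
  rho <- if (free_rho) tanh(theta[p + k + 1]) else fix_rho
  H <- tryCatch(stats::optimHess(theta, negll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  np <- length(theta)
  se <- rep(NA_real_, p + k + 3)
  se_a <- NA_real_
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
    se_th <- sqrt(diag(vc))
    se_rho <- if (free_rho) (1 - rho^2) * se_th[np] else NA_real_
    se_a <- if (free_rho) se_th[np] else NA_real_
    se <- c(se_th[seq_len(p)], se_th[p + seq_len(k)], se_rho, NA_real_,
            se_rho)
  }
  names(se) <- .named_se(beta, gamma)
  fit <- .heckman_fit(beta, gamma, rho, 1, se, loglik = -opt$value,
                      converged = opt$convergence == 0L,
                      method = "probit_fiml",
                      extra = list(se_atanh_rho = se_a,
                                   n_selected = sum(s1),
                                   n_total = length(data$s)))
  if (!is.null(margin_var)) {
    if (!margin_var %in% colnames(data$X))
      stop("heckman_probit_fiml: unknown margin_var '", margin_var, "'",
           call. = FALSE)
    X1 <- data$X; X1[, margin_var] <- 1
    X0 <- data$X; X0[, margin_var] <- 0
    fit$margin <- list(var = margin_var,
                       ame = mean(stats::pnorm(drop(X1 %*% beta)) -
                                    stats::pnorm(drop(X0 %*% beta))))
  }
  fit
}
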