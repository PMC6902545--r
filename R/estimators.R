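# OLS and probit building blocks shared by every selection estimator.

#' Bundle outcome and selection designs for a selection-model fit
#'
#' Builds the `(y, X, s, Z)` design bundle. The outcome covariates `x_cols`
#' must be a subset of the selection covariates `z_cols`; if no selection
#' covariate lies outside the outcome equation, identification rests on the
#' nonlinearity of the inverse Mills ratio alone and an exclusion-restriction
#' warning is raised (not an error).
#'
#' @param data A data frame (e.g. a [generate_complete()] cohort).
#' @param outcome Name of the outcome column (may contain `NA`).
#' @param x_cols Outcome-equation covariate columns.
#' @param select Optional name of a 0/1 selection column; when omitted the
#'   indicator is derived from outcome presence.
#' @param z_cols Selection-equation covariate columns (default `x_cols`).
#' @param intercept Add an intercept column to both designs.
#' @return An object of class `model_data`: list with elements `y`, `X`, `s`,
#'   `Z`.
#' @export
model_data <- function(data, outcome, x_cols, select = NULL,
                       z_cols = x_cols, intercept = TRUE) {
  for (cl in c(outcome, x_cols, z_cols, select))
    if (!cl %in% names(data))
      stop("model_data: column '", cl, "' not found; available: ",
           paste(names(data), collapse = ", "), call. = FALSE)
  if (!all(x_cols %in% z_cols))
    stop("model_data: outcome covariates must be a subset of selection ",
         "covariates; offending: ",
         paste(setdiff(x_cols, z_cols), collapse = ", "), call. = FALSE)
  y <- as.numeric(data[[outcome]])
  s <- if (is.null(select)) as.integer(!is.na(y)) else {
    si <- as.integer(data[[select]])
    if (!all(si %in% c(0L, 1L)))
      stop("model_data: selection column must be 0/1", call. = FALSE)
    if (!identical(si == 1L, !is.na(y)))
      stop("model_data: selection column contradicts outcome presence ",
           "(y must be present exactly where select = 1)", call. = FALSE)
    si
  }
  covs <- unique(c(x_cols, z_cols))
  if (anyNA(data[, covs, drop = FALSE]))
    stop("model_data: missing values in covariate columns are not ",
         "supported (only the outcome may be missing)", call. = FALSE)
  mk <- function(cols) {
    m <- as.matrix(data[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    if (intercept) m <- cbind("(Intercept)" = 1, m)
    m
  }
  if (!length(setdiff(z_cols, x_cols)))
    warning("model_data: no selection covariate excluded from the outcome ",
            "equation; the selection model is identified only by the ",
            "nonlinearity of the inverse Mills ratio", call. = FALSE)
  structure(list(y = y, X = mk(x_cols), s = s, Z = mk(z_cols)),
            class = "model_data")
}

#' @export
print.model_data <- function(x, ...) {
  cat(sprintf("model_data: %d rows (%d selected)\n", length(x$s), sum(x$s)))
  cat("  outcome design: ", paste(colnames(x$X), collapse = ", "), "\n")
  cat("  selection design:", paste(colnames(x$Z), collapse = ", "), "\n")
  invisible(x)
}

.fit_result <- function(coef, se, n_used, loglik = NA_real_,
                        converged = TRUE, extra = list()) {
  z <- stats::qnorm(0.975)
  out <- c(list(coef = coef, se = se, ci_low = coef - z * se,
                ci_high = coef + z * se, n_used = n_used, loglik = loglik,
                converged = converged), extra)
  class(out) <- "hm_fit"
  out
}

#' @export
print.hm_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coef, se = x$se, ci_low = x$ci_low,
                    ci_high = x$ci_high)
  print(round(tab, 4))
  cat(sprintf("n used = %d", x$n_used))
  if (is.finite(x$loglik)) cat(sprintf(", log-likelihood = %.3f", x$loglik))
  if (!x$converged) cat("  [NOT converged]")
  cat("\n")
  invisible(x)
}

#' Ordinary least squares on a model-data bundle
#'
#' Closed-form least squares with conventional homoskedastic standard errors
#' and Wald 95% intervals. With `use_selected_only = TRUE` this is the
#' complete-case analysis: only rows with an observed outcome enter.
#'
#' @param data A [model_data()] bundle.
#' @param use_selected_only Restrict to rows with `s = 1` (complete cases).
#' @return An `hm_fit` with named `coef`, `se`, `ci_low`, `ci_high`, and a
#'   `vcov` matrix.
#' @export
fit_ols <- function(data, use_selected_only = TRUE) {
  rows <- if (use_selected_only) data$s == 1L else rep(TRUE, length(data$s))
  y <- data$y[rows]; X <- data$X[rows, , drop = FALSE]
  if (!use_selected_only && anyNA(y))
    stop("fit_ols: outcome has missing values; use use_selected_only = TRUE",
         call. = FALSE)
  if (!length(y)) stop("fit_ols: zero usable rows", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fit_ols: singular design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  cf <- qr.coef(qx, y)
  res <- y - drop(X %*% cf)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  vcov <- sigma2 * XtX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  .fit_result(cf, sqrt(diag(vcov)), length(y),
              extra = list(vcov = vcov, sigma = sqrt(sigma2),
                           residuals = res, df = df))
}

#' Inverse Mills ratio
#'
#' `lambda(u) = phi(u) / Phi(u)`, the mean of a standard normal truncated
#' below at `-u`. Computed on the log scale so it stays accurate deep into
#' the lower tail (for `u -> -Inf`, `lambda(u) ~ -u`).
#'
#' @param u Numeric scalar or vector (finite).
#' @return `lambda(u)`, same shape as `u`.
#' @export
inverse_mills <- function(u) {
  if (any(!is.finite(u))) stop("inverse_mills: input must be finite",
                               call. = FALSE)
  exp(stats::dnorm(u, log = TRUE) - stats::pnorm(u, log.p = TRUE))
}

# Probit log-likelihood and derivatives for Newton iterations.
.probit_ll <- function(gamma, s, Z) {
  q <- drop(Z %*% gamma)
  sum(stats::pnorm(ifelse(s == 1L, q, -q), log.p = TRUE))
}

#' Probit regression by Newton's method
#'
#' Maximum-likelihood probit with analytic gradient and Hessian; convergence
#' when the maximum absolute score falls below `tol` (default 1e-8), at most
#' `max_iter` iterations with step-halving.
#'
#' @param s 0/1 response vector containing both classes.
#' @param Z Design matrix (with intercept column if wanted).
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An `hm_fit` with `coef`, `se`, `vcov`, `loglik`, `converged`.
#' @export
fit_probit <- function(s, Z, tol = 1e-8, max_iter = 100L) {
  s <- as.integer(s)
  if (all(s == 1L) || all(s == 0L))
    stop("fit_probit: degenerate outcome (response is all ",
         s[1], "s)", call. = FALSE)
  k <- ncol(Z)
  gamma <- numeric(k)
  ll <- .probit_ll(gamma, s, Z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- drop(Z %*% gamma)
    if (min(q[s == 1L]) > 8 && max(q[s == 0L]) < -8) {
      sep_name <- if (ncol(Z) > 1)
        colnames(Z)[-1][which.max(abs(gamma[-1] *
          apply(Z[, -1, drop = FALSE], 2, stats::sd)))]
      else colnames(Z)[1]
      stop("fit_probit: perfect separation of the response by '", sep_name,
           "'; the ML estimate does not exist", call. = FALSE)
    }
    lam1 <- inverse_mills(q)     # score weight for s = 1
    lam0 <- inverse_mills(-q)    # for s = 0
    u <- ifelse(s == 1L, lam1, -lam0)
    grad <- drop(crossprod(Z, u))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- ifelse(s == 1L, lam1 * (lam1 + q), lam0 * (lam0 - q))
    H <- crossprod(Z * w, Z)
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("fit_probit: singular Hessian (possible perfect separation by '",
           colnames(Z)[which.max(abs(gamma))], "')", call. = FALSE))
    # step-halve until the likelihood does not decrease
    for (h in 0:30) {
      cand <- gamma + step / 2^h
      ll_new <- .probit_ll(cand, s, Z)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    gamma <- cand; ll <- ll_new
  }
  if (!converged) {
    sep_col <- colnames(Z)[which.max(abs(gamma))]
    stop("fit_probit: no convergence in ", max_iter,
         " iterations (perfect separation suspected, largest coefficient ",
         "on '", sep_col, "')", call. = FALSE)
  }
  q <- drop(Z %*% gamma)
  # a "converged" fit that classifies every row essentially perfectly is a
  # separation artefact: the score vanishes as the coefficients diverge
  if (min(q[s == 1L]) > 5 && max(q[s == 0L]) < -5) {
    sep_name <- if (ncol(Z) > 1)
      colnames(Z)[-1][which.max(abs(gamma[-1] *
        apply(Z[, -1, drop = FALSE], 2, stats::sd)))]
    else colnames(Z)[1]
    stop("fit_probit: perfect separation of the response by '", sep_name,
         "'; the ML estimate does not exist", call. = FALSE)
  }
  lam1 <- inverse_mills(q); lam0 <- inverse_mills(-q)
  w <- ifelse(s == 1L, lam1 * (lam1 + q), lam0 * (lam0 - q))
  vcov <- solve(crossprod(Z * w, Z))
  dimnames(vcov) <- list(colnames(Z), colnames(Z))
  names(gamma) <- colnames(Z)
  .fit_result(gamma, sqrt(diag(vcov)), length(s), loglik = ll,
              converged = TRUE, extra = list(vcov = vcov))
}

#' Average marginal effect from a probit fit
#'
#' For a continuous column the average of `phi(z'gamma) * gamma_v` over the
#' sample; for a binary 0/1 column the average discrete change
#' `Phi(z'gamma | v = 1) - Phi(z'gamma | v = 0)`. Standard error by the delta
#' method.
#'
#' @param fit A [fit_probit()] result.
#' @param Z The design matrix the effect is averaged over.
#' @param var_name Name of the fitted column of interest.
#' @return List with `ame`, `se`, `ci_low`, `ci_high`, `type`.
#' @export
probit_margins <- function(fit, Z, var_name) {
  gamma <- fit$coef
  if (!var_name %in% names(gamma))
    stop("probit_margins: unknown column '", var_name, "'; fitted: ",
         paste(names(gamma), collapse = ", "), call. = FALSE)
  v <- match(var_name, colnames(Z))
  binary <- all(Z[, v] %in% c(0, 1))
  if (binary) {
    Z1 <- Z; Z1[, v] <- 1
    Z0 <- Z; Z0[, v] <- 0
    q1 <- drop(Z1 %*% gamma); q0 <- drop(Z0 %*% gamma)
    ame <- mean(stats::pnorm(q1) - stats::pnorm(q0))
    g <- colMeans(stats::dnorm(q1) * Z1 - stats::dnorm(q0) * Z0)
  } else {
    q <- drop(Z %*% gamma)
    phi <- stats::dnorm(q)
    ame <- mean(phi) * gamma[v]
    g <- colMeans(-q * phi * Z) * gamma[v]
    g[v] <- g[v] + mean(phi)
  }
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  zc <- stats::qnorm(0.975)
  list(ame = unname(ame), se = se, ci_low = unname(ame) - zc * se,
       ci_high = unname(ame) + zc * se,
       type = if (binary) "discrete" else "continuous", var = var_name)
}
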