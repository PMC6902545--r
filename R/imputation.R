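# Comparison methods for missing outcomes: mean imputation, pattern
# imputation with delta adjustment (PIDA), Bayesian normal-linear multiple
# imputation with Rubin's-rules pooling.

#' Replace missing outcomes with the overall observed mean
#'
#' @param data A data frame (cohort schema or any table).
#' @param outcome Name of the outcome column with missing values.
#' @return The data frame with the outcome column completed; observed values
#'   are untouched.
#' @export
mean_impute <- function(data, outcome = "bw_obs") {
  y <- data[[outcome]]
  if (all(is.na(y)))
    stop("mean_impute: no observed values in '", outcome, "'", call. = FALSE)
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  data[[outcome]] <- y
  data
}

#' Specification for pattern imputation with delta adjustment
#'
#' Two deterministic fill strategies used as sensitivity analyses:
#' `"shift"` fills every missing outcome with
#' `observed mean + shift_sd * observed SD` (so `shift_sd = -0.5` and `+0.5`
#' are the half-SD-below and half-SD-above scenarios); `"group_mean"` fills
#' with the observed mean of the subject's own treatment group.
#'
#' @param strategy `"group_mean"` or `"shift"`.
#' @param shift_sd Signed multiple of the observed SD (strategy `"shift"`).
#' @param group_col Name of the grouping (treatment) column (strategy
#'   `"group_mean"`).
#' @return A `pida_spec` list.
#' @export
pida_spec <- function(strategy = c("shift", "group_mean"), shift_sd = -0.5,
                      group_col = "treat") {
  strategy <- match.arg(strategy)
  if (strategy == "shift" && !is.finite(shift_sd))
    stop("pida_spec: shift_sd must be finite", call. = FALSE)
  structure(list(strategy = strategy, shift_sd = shift_sd,
                 group_col = group_col), class = "pida_spec")
}

#' Pattern imputation with delta adjustment
#'
#' Deterministic single imputation per [pida_spec()]: a constant fill value
#' (observed mean shifted by a chosen delta) or the group-specific observed
#' mean. No noise is added; observed values are untouched.
#'
#' @param data A data frame.
#' @param spec A [pida_spec()].
#' @param outcome Name of the outcome column with missing values.
#' @return The completed data frame.
#' @export
pida_impute <- function(data, spec = pida_spec(), outcome = "bw_obs") {
  stopifnot(inherits(spec, "pida_spec"))
  y <- data[[outcome]]
  if (all(is.na(y)))
    stop("pida_impute: no observed values in '", outcome, "'", call. = FALSE)
  miss <- is.na(y)
  if (spec$strategy == "shift") {
    y[miss] <- mean(y, na.rm = TRUE) + spec$shift_sd * stats::sd(y, na.rm = TRUE)
  } else {
    if (!spec$group_col %in% names(data))
      stop("pida_impute: group column '", spec$group_col, "' not found",
           call. = FALSE)
    g <- data[[spec$group_col]]
    for (lev in unique(g[miss])) {
      obs_g <- y[!miss & g == lev]
      if (!length(obs_g))
        stop("pida_impute: group '", lev, "' has no observed outcome",
             call. = FALSE)
      y[miss & g == lev] <- mean(obs_g)
    }
  }
  data[[outcome]] <- y
  data
}

#' Multiple imputation of a single incomplete outcome
#'
#' Bayesian normal linear-regression imputation: for each of `m` imputations
#' the residual variance is drawn from its scaled inverse-chi-square
#' posterior, the regression coefficients from their conditional normal
#' posterior, and every missing outcome is filled with its linear prediction
#' plus normal noise at the drawn SD. With a single incomplete variable the
#' chained-equations cycle has exactly one step, so this *is* the full MICE
#' procedure for this data pattern. Deterministic given `seed`.
#'
#' @param data A data frame; only `outcome` may contain missing values.
#' @param m Number of imputations (default 150).
#' @param seed RNG seed.
#' @param outcome Name of the incomplete outcome column.
#' @param predictors Complete predictor columns for the imputation model.
#' @return List of `m` completed data frames.
#' @export
mice_impute <- function(data, m = 150L, seed = 1L, outcome = "bw_obs",
                        predictors = c("treat", "distance")) {
  y <- data[[outcome]]
  miss <- is.na(y)
  W <- cbind("(Intercept)" = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  storage.mode(W) <- "double"
  if (anyNA(W))
    stop("mice_impute: predictor columns must be complete", call. = FALSE)
  Wo <- W[!miss, , drop = FALSE]; yo <- y[!miss]
  kk <- ncol(Wo); no <- length(yo)
  qx <- qr(Wo)
  if (qx$rank < kk)
    stop("mice_impute: singular predictor matrix", call. = FALSE)
  bhat <- qr.coef(qx, yo)
  rss <- sum((yo - drop(Wo %*% bhat))^2)
  V <- chol2inv(qr.R(qx))
  L <- t(chol(V + diag(1e-300, kk)))
  Wm <- W[miss, , drop = FALSE]
  set.seed(.sub_seed(seed, "impute"))
  lapply(seq_len(m), function(i) {
    sigma2_star <- rss / stats::rchisq(1, df = no - kk)
    beta_star <- bhat + sqrt(sigma2_star) * drop(L %*% stats::rnorm(kk))
    filled <- y
    filled[miss] <- drop(Wm %*% beta_star) +
      stats::rnorm(sum(miss), 0, sqrt(sigma2_star))
    out <- data
    out[[outcome]] <- filled
    out
  })
}

#' Write multiple imputations as one long-format CSV
#'
#' Stacks the `m` completed datasets with an `imp` index column.
#'
#' @param imps List of completed data frames from [mice_impute()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_imputations <- function(imps, path) {
  long <- do.call(rbind, lapply(seq_along(imps), function(i)
    cbind(imp = i, as.data.frame(imps[[i]]))))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pool a scalar estimand across imputations by Rubin's rules
#'
#' `estimate` is the mean of the per-imputation estimates; `within_var` the
#' mean of their variances; `between_var` the sample variance of the
#' estimates; `total_var = within + (1 + 1/m) * between`; degrees of freedom
#' by the standard large-sample formula
#' `(m - 1) * (1 + within / ((1 + 1/m) * between))^2`; the interval is a
#' t interval on `total_var` with those df.
#'
#' @param estimates Numeric vector of per-imputation estimates (length >= 2).
#' @param variances Numeric vector of per-imputation squared standard errors.
#' @return A `pooled_estimate` list with fields `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `ci_low`, `ci_high`, `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2L || length(variances) != m)
    stop("rubin_pool: need m >= 2 estimates with matching variances",
         call. = FALSE)
  if (any(!is.finite(estimates)) || any(!is.finite(variances)))
    stop("rubin_pool: estimates and variances must be finite", call. = FALSE)
  est <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between > 0)
    (m - 1) * (1 + within / ((1 + 1 / m) * between))^2 else Inf
  tq <- stats::qt(0.975, df)
  structure(list(estimate = est, within_var = within, between_var = between,
                 total_var = total, df = df,
                 ci_low = est - tq * sqrt(total),
                 ci_high = est + tq * sqrt(total), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate over m = %d imputations\n", x$m))
  cat(sprintf("  estimate = %.4f (95%% CI %.4f, %.4f)\n",
              x$estimate, x$ci_low, x$ci_high))
  cat(sprintf("  within = %.4g, between = %.4g, total = %.4g, df = %.1f\n",
              x$within_var, x$between_var, x$total_var, x$df))
  invisible(x)
}
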