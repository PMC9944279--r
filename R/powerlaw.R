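#' Fit a power law U = a d^b to size~velocity data
#'
#' Two routes are offered. `"loglog_ols"` regresses log10(u) on log10(d) by
#' ordinary least squares (the route used for the fractal dimension, whose
#' estimator is defined on log-transformed data). `"nonlinear_ls"` minimises
#' the untransformed residual sum of squares with a Levenberg-Marquardt
#' fit initialised from the log-log solution; it is the default for display
#' fits of the size~velocity relation, where absolute velocity residuals are
#' the natural loss.
#'
#' @param data data frame with the predictor and response columns.
#' @param d,u column names (unquoted) of diameter and velocity; defaults
#'   `d_mm` and `u_m_d`.
#' @param method `"nonlinear_ls"` (default) or `"loglog_ols"`.
#' @return an object of class `agg_powerfit` with elements `a`, `b`, `se_b`,
#'   `residual_ss` (in the fit's own space), `n`, `method`, `data`.
#' @examples
#' dat <- tibble::tibble(d_mm = 1:5, u_m_d = 2 * (1:5)^1.5)
#' fit_power_law(dat, method = "loglog_ols")
#' @export
fit_power_law <- function(data, d = d_mm, u = u_m_d,
                          method = c("nonlinear_ls", "loglog_ols")) {
  method <- match.arg(method)
  dv <- dplyr::pull(data, {{ d }})
  uv <- dplyr::pull(data, {{ u }})
  if (length(dv) < 3) {
    abort_config("power-law fit requires at least 3 observations")
  }
  if (any(!is.finite(dv)) || any(!is.finite(uv)) || any(dv <= 0) || any(uv <= 0)) {
    abort_config("power-law fit requires positive, finite d and u")
  }

  logfit <- lm(log10(uv) ~ log10(dv))
  a_log <- 10^coef(logfit)[[1]]
  b_log <- coef(logfit)[[2]]

  if (method == "loglog_ols") {
    # noiseless inputs are legitimate (oracle data); silence the
    # "essentially perfect fit" note
    sm <- suppressWarnings(summary(logfit))
    out <- list(a = a_log, b = b_log,
                se_b = sm$coefficients[2, 2],
                residual_ss = sum(resid(logfit)^2),
                r_squared = sm$r.squared,
                n = length(dv), method = method,
                data = tibble(d = dv, u = uv))
  } else {
    nl <- minpack.lm::nlsLM(uv ~ a * dv^b,
                            start = list(a = a_log, b = b_log),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    sm <- summary(nl)
    out <- list(a = coef(nl)[["a"]], b = coef(nl)[["b"]],
                se_b = sm$coefficients["b", "Std. Error"],
                residual_ss = sum(resid(nl)^2),
                r_squared = 1 - sum(resid(nl)^2) / sum((uv - mean(uv))^2),
                n = length(dv), method = method,
                data = tibble(d = dv, u = uv))
  }
  structure(out, class = "agg_powerfit")
}

#' @export
print.agg_powerfit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): u = %.4g * d^%.4g  (n = %d, se_b = %.3g)\n",
              x$method, x$a, x$b, x$n, x$se_b))
  invisible(x)
}

#' Predict velocities from a fitted power law
#'
#' @param object an `agg_powerfit`.
#' @param newdata optional data frame with a `d` column (or numeric vector
#'   via `d`); defaults to the training diameters.
#' @param d numeric vector of diameters, used when `newdata` is missing.
#' @param ... unused.
#' @return numeric vector of predicted velocities.
#' @export
predict.agg_powerfit <- function(object, newdata = NULL, d = NULL, ...) {
  dv <- if (!is.null(newdata)) newdata$d else d %||% object$data$d
  object$a * dv^object$b
}

#' Three-dimensional fractal number of aggregates from settling data
#'
#' Aggregate porosity increases with size, so settling velocity scales as
#' U ~ d^(D3 - 1) where D3 is the three-dimensional fractal number (D3 = 3
#' for solid spheres in the Stokes regime, smaller for looser structures).
#' D3 is estimated as one plus the slope of the log10-log10 OLS regression
#' of velocity on diameter; the slope's standard error carries over.
#'
#' @param data data frame with diameter and velocity columns.
#' @param d,u column names (unquoted); defaults `d_mm`, `u_m_d`.
#' @return one-row tibble with `d3`, `se`, `n`.
#' @examples
#' dat <- tibble::tibble(d_mm = c(1, 2, 3, 4), u_m_d = 60 * c(1, 2, 3, 4)^1.37)
#' fractal_dimension(dat) # d3 = 2.37
#' @export
fractal_dimension <- function(data, d = d_mm, u = u_m_d) {
  fit <- fit_power_law(data, {{ d }}, {{ u }}, method = "loglog_ols")
  tibble(d3 = fit$b + 1, se = fit$se_b, n = fit$n)
}

#' Compare size~velocity curve fits between two groups
#'
#' Extra-sum-of-squares F-test of a pooled single power law against separate
#' per-group power laws. By default the comparison is made in log space so
#' that it matches the OLS framework of the log-log estimator; `space =
#' "linear"` compares nonlinear least-squares fits instead. The pooled model
#' has 2 parameters and the separate model 4, so the test has
#' df1 = 2 and df2 = n - 4.
#'
#' @param group1,group2 data frames with diameter and velocity columns
#'   (`d_mm`, `u_m_d` by default).
#' @param d,u column names (unquoted).
#' @param space `"log"` (default) or `"linear"`.
#' @return one-row tibble with `f`, `df1`, `df2`, `p`, `ss_pooled`,
#'   `ss_separate`, `n`.
#' @export
compare_fits <- function(group1, group2, d = d_mm, u = u_m_d,
                         space = c("log", "linear")) {
  space <- match.arg(space)
  method <- if (space == "log") "loglog_ols" else "nonlinear_ls"
  f1 <- fit_power_law(group1, {{ d }}, {{ u }}, method = method)
  f2 <- fit_power_law(group2, {{ d }}, {{ u }}, method = method)
  pooled_data <- tibble(
    d_mm = c(f1$data$d, f2$data$d),
    u_m_d = c(f1$data$u, f2$data$u)
  )
  fp <- fit_power_law(pooled_data, method = method)

  ss_sep <- f1$residual_ss + f2$residual_ss
  ss_pool <- fp$residual_ss
  n <- f1$n + f2$n
  df1 <- 2L
  df2 <- n - 4L
  if (df2 < 1 || ss_sep <= 0) {
    abort_config("degenerate fits: cannot form the F statistic")
  }
  f_stat <- ((ss_pool - ss_sep) / df1) / (ss_sep / df2)
  f_stat <- max(f_stat, 0) # guard tiny negative from nls convergence noise
  tibble(f = f_stat, df1 = df1, df2 = df2,
         p = pf(f_stat, df1, df2, lower.tail = FALSE),
         ss_pooled = ss_pool, ss_separate = ss_sep, n = n)
}
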