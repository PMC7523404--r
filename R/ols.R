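#' Ordinary least-squares fit with slope inference
#'
#' Fits `y = m*x + b` by OLS and records everything the downstream
#' relative-expression transforms need: slope, intercept, r-squared, the
#' slope's standard error and t-based confidence interval, the two-sided
#' p-value for the null hypothesis m = 0, and the observed x-range (used
#' later to refuse extrapolation). The slope CI is the single source of
#' uncertainty for every confidence band this package produces.
#'
#' @param data A data frame; by default its first column is the predictor
#'   and its second the response.
#' @param x,y Optional unquoted column names selecting predictor and
#'   response.
#' @param conf_level Confidence level for the slope interval (default
#'   0.95).
#' @param log_x,log_y If `TRUE`, the corresponding variable is
#'   log10-transformed before fitting (values must be positive). Supply
#'   raw-scale data; the transform is internal, and the stored x-range and
#'   baseline statistics stay on the raw scale so that downstream curves
#'   take raw-scale inputs.
#'
#' @return An object of class `cb_fit`: a list with elements `m`, `b`,
#'   `r2`, `se_m`, `df` (residual degrees of freedom, n - 2), `ci`
#'   (c(L, U)), `conf_level`, `p_slope`, `n`, `x_min`/`x_max` (raw scale),
#'   `log_x`, `log_y`, the raw data, and the underlying `lm` fit.
#'   Residual variance uses the unbiased divisor n - 2.
#'
#' @examples
#' fit <- fit_ols(demo_table(1))
#' fit
#' tidy(fit)
#' glance(fit)
#' @export
fit_ols <- function(data, x = NULL, y = NULL, conf_level = 0.95,
                    log_x = FALSE, log_y = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (conf_level <= 0 || conf_level >= 1) {
    abort("`conf_level` must be strictly between 0 and 1.")
  }
  xq <- enquo(x)
  yq <- enquo(y)
  xv <- if (quo_is_null(xq)) data[[1]] else eval_tidy(xq, data)
  yv <- if (quo_is_null(yq)) data[[2]] else eval_tidy(yq, data)
  if (!is.numeric(xv) || !is.numeric(yv)) {
    abort("Predictor and response columns must be numeric.")
  }
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("Insufficient points: at least 3 complete (x, y) pairs are required.")
  if (length(unique(xv)) < 2) {
    abort("Degenerate predictor: x has no variance.")
  }
  if (log_x && any(xv <= 0)) abort("log_x = TRUE requires positive x values.")
  if (log_y && any(yv <= 0)) abort("log_y = TRUE requires positive y values.")
  xt <- if (log_x) log10(xv) else xv
  yt <- if (log_y) log10(yv) else yv

  model <- lm(yt ~ xt)
  sm <- quiet_perfect(summary(model))
  ci <- quiet_perfect(unname(confint(model, "xt", level = conf_level)))

  structure(
    list(
      m = unname(coef(model)[["xt"]]),
      b = unname(coef(model)[["(Intercept)"]]),
      r2 = sm$r.squared,
      se_m = sm$coefficients["xt", "Std. Error"],
      df = model$df.residual,
      conf_level = conf_level,
      ci = c(ci[1], ci[2]),
      p_slope = sm$coefficients["xt", "Pr(>|t|)"],
      n = n,
      x_min = min(xv),
      x_max = max(xv),
      log_x = log_x,
      log_y = log_y,
      data = tibble(x = xv, y = yv),
      model = model
    ),
    class = "cb_fit"
  )
}

#' @export
print.cb_fit <- function(x, digits = 4, ...) {
  scale_note <- paste0(
    if (x$log_x) "log10(x)" else "x", " -> ",
    if (x$log_y) "log10(y)" else "y"
  )
  cat("Linear fit (", scale_note, "), n = ", x$n, "\n", sep = "")
  cat("  slope m     = ", signif(x$m, digits),
      "  [", signif(x$ci[1], digits), ", ", signif(x$ci[2], digits),
      "] (", format(100 * x$conf_level), "% CI)\n", sep = "")
  cat("  intercept b = ", signif(x$b, digits), "\n", sep = "")
  cat("  r^2 = ", signif(x$r2, digits),
      ", p(slope = 0) = ", format.pval(x$p_slope, digits = 3),
      ", x range [", signif(x$x_min, digits), ", ",
      signif(x$x_max, digits), "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.cb_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  ci <- confint(x$model, level = x$conf_level)
  tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$b, x$m),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )
}

#' @export
glance.cb_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    sigma = summary(x$model)$sigma,
    statistic = (x$m / x$se_m)^2,
    p.value = x$p_slope,
    df.residual = x$df,
    nobs = x$n,
    conf.level = x$conf_level
  )
}

#' Test whether a fitted slope is indistinguishable from zero
#'
#' When the slope test cannot reject m = 0, the fitted relationship
#' degenerates to a constant and the predicted relative expression ratio
#' is 1 everywhere: no evidence that the covariate affects expression.
#' Curve builders attach this flag so reports can state that
#' interpretation (see the `null_as_unity` option of [ratio_curve()]).
#'
#' @param fit A [fit_ols()] result.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` when the two-sided slope p-value is >= `alpha`.
#' @export
slope_is_null <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cb_fit"))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  is.na(fit$p_slope) || fit$p_slope >= alpha
}
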