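#' Relative expression ratio as a function of the covariate
#'
#' Transforms a regression of weighted delta-Cq (the dependent variable)
#' on a covariate x into a relative-expression curve anchored at a
#' baseline x0. With an untransformed covariate the curve is exponential:
#' \deqn{\hat R = 10^{m (x_0 - x)}}
#' with confidence band obtained by substituting the slope CI bounds
#' (L, U) for m and ordering the two results at each point (which bound is
#' lower flips with the sign of x - x0). When the fit used
#' `log_x = TRUE` the same propagation yields a power law:
#' \deqn{\hat R = (x_0 / x)^m}
#' with band endpoints \eqn{(x_0/x)^L} and \eqn{(x_0/x)^U}. In both forms
#' R(x0) = 1 exactly, with a degenerate (zero-width) interval there:
#' the only random element in the prediction is the slope, so the band
#' width grows with distance from the baseline and is zero at it.
#'
#' @param fit A [fit_ols()] result with delta-Cq as the response
#'   (`log_y` must be `FALSE`).
#' @param baseline A [choose_baseline()] result; defaults to the mean
#'   policy.
#' @param at Raw-scale covariate values at which to evaluate the curve;
#'   defaults to the observed x values. Values outside the observed range
#'   are refused unless `allow_extrapolation = TRUE` (then a warning).
#' @param grid_size If not `NULL`, `grid_size` evenly spaced values across
#'   the observed range are appended to `at`.
#' @param allow_extrapolation Permit evaluation outside the observed x
#'   range (with a warning). Off by default: the fitted line has no
#'   support outside the data.
#' @param null_as_unity If `TRUE` and the slope is not distinguishable
#'   from zero at `1 - conf_level`, report R = 1 with a degenerate band
#'   everywhere (the no-evidence convention). By default the fitted curve
#'   is returned unchanged and only the `null_slope` attribute is set, so
#'   that information is not silently destroyed.
#'
#' @return A tibble of class `cb_curve` with columns `x`, `r_hat`,
#'   `ci_low`, `ci_high` and attributes `mode` ("exponential" or
#'   "power_x"), `baseline`, `m`, `ci`, `conf_level`, `null_slope`.
#'
#' @examples
#' fit <- fit_ols(demo_table(1))
#' ratio_curve(fit, at = 8.85) # expression ~27% below the mean-x baseline
#' @export
ratio_curve <- function(fit, baseline = choose_baseline(fit), at = NULL,
                        grid_size = NULL, allow_extrapolation = FALSE,
                        null_as_unity = FALSE) {
  stopifnot(inherits(fit, "cb_fit"), inherits(baseline, "cb_baseline"))
  if (fit$log_y) {
    abort("ratio_curve() needs delta-Cq as the response; this fit log-transformed y.")
  }
  x <- curve_inputs(fit, at, grid_size, allow_extrapolation)
  if (fit$log_x) {
    if (any(x <= 0)) abort("Covariate values must be positive for a log-x fit.")
    ratio <- baseline$x0 / x
    r_hat <- ratio^fit$m
    lo <- pmin(ratio^fit$ci[1], ratio^fit$ci[2])
    hi <- pmax(ratio^fit$ci[1], ratio^fit$ci[2])
    mode <- "power_x"
  } else {
    d <- baseline$x0 - x
    r_hat <- 10^(fit$m * d)
    lo <- pmin(10^(fit$ci[1] * d), 10^(fit$ci[2] * d))
    hi <- pmax(10^(fit$ci[1] * d), 10^(fit$ci[2] * d))
    mode <- "exponential"
  }
  null_slope <- slope_is_null(fit, 1 - fit$conf_level)
  out <- tibble(x = x, r_hat = r_hat, ci_low = lo, ci_high = hi)
  if (null_as_unity && null_slope) {
    out$r_hat <- out$ci_low <- out$ci_high <- rep(1, nrow(out))
  }
  new_cb_curve(out, mode, fit, baseline, null_slope)
}

#' Expression of one gene as a power of another's expression ratio
#'
#' For a regression of gene B's weighted delta-Cq on gene A's, the fitted
#' slope links their relative expression ratios as a power law:
#' \deqn{\hat R_B = R_A^{\,m}}
#' with confidence band endpoints \eqn{R_A^L} and \eqn{R_A^U} ordered at
#' each point (which is lower flips at R_A = 1). At R_A = 1 the predicted
#' ratio is exactly 1 with a degenerate interval.
#'
#' @param fit A [fit_ols()] of gene B's delta-Cq (response) on gene A's
#'   delta-Cq (predictor); no log transforms.
#' @param ratio_a Positive relative expression ratios of gene A at which
#'   to predict gene B's ratio.
#' @inheritParams ratio_curve
#' @return A tibble of class `cb_curve` with columns `ratio_a`, `r_hat`,
#'   `ci_low`, `ci_high` (mode `"power_gene"`).
#' @examples
#' fit <- fit_ols(demo_table(5))
#' gene_ratio_curve(fit, ratio_a = 1.1)
#' @export
gene_ratio_curve <- function(fit, ratio_a, baseline = choose_baseline(fit),
                             null_as_unity = FALSE) {
  stopifnot(inherits(fit, "cb_fit"), inherits(baseline, "cb_baseline"))
  if (fit$log_x || fit$log_y) {
    abort("gene_ratio_curve() expects an untransformed delta-Cq vs delta-Cq fit.")
  }
  if (!is.numeric(ratio_a) || any(!is.finite(ratio_a)) || any(ratio_a <= 0)) {
    abort("`ratio_a` must be finite and > 0.")
  }
  r_hat <- ratio_a^fit$m
  lo <- pmin(ratio_a^fit$ci[1], ratio_a^fit$ci[2])
  hi <- pmax(ratio_a^fit$ci[1], ratio_a^fit$ci[2])
  null_slope <- slope_is_null(fit, 1 - fit$conf_level)
  out <- tibble(ratio_a = ratio_a, r_hat = r_hat, ci_low = lo, ci_high = hi)
  if (null_as_unity && null_slope) {
    out$r_hat <- out$ci_low <- out$ci_high <- rep(1, nrow(out))
  }
  new_cb_curve(out, "power_gene", fit, baseline, null_slope)
}

#' Predicted response at a given relative expression ratio
#'
#' Inverts a regression in which weighted delta-Cq is the *independent*
#' variable: given a target relative expression ratio R (relative to the
#' delta-Cq baseline x0), predict the response. With an untransformed
#' response the relationship is logarithmic:
#' \deqn{\hat y = \hat y_0 - m \log_{10}(R), \qquad \hat y_0 = m x_0 + b}
#' and the confidence band substitutes the slope CI (L, U) for m, with the
#' bound order swapping when log10(R) changes sign. When the fit used
#' `log_y = TRUE` the back-transformed relationship is a power function:
#' \deqn{\hat y = \hat y_0 R^{-m}, \qquad \hat y_0 = 10^{m x_0 + b}}
#' with band endpoints \eqn{\hat y_0 R^{-L}} and \eqn{\hat y_0 R^{-U}}.
#' At R = 1 the prediction equals the baseline response with a degenerate
#' interval. Predictions are specific to the chosen baseline: an R of 1.5
#' means 50% higher expression than at x0.
#'
#' @param fit A [fit_ols()] with delta-Cq as the predictor (`log_x` must
#'   be `FALSE`).
#' @param ratio Positive relative expression ratios.
#' @inheritParams ratio_curve
#' @return A tibble of class `cb_response` with columns `ratio`, `y_hat`,
#'   `ci_low`, `ci_high`; attributes include `y0_hat` and `mode`
#'   ("log" or "power_y").
#' @examples
#' fit <- fit_ols(demo_table(4))
#' response_curve(fit, ratio = 1.5) # change in huddling time at R = 1.5
#' @export
response_curve <- function(fit, ratio, baseline = choose_baseline(fit)) {
  stopifnot(inherits(fit, "cb_fit"), inherits(baseline, "cb_baseline"))
  if (fit$log_x) {
    abort("response_curve() needs delta-Cq as the predictor; this fit log-transformed x.")
  }
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort("`ratio` must be finite and > 0.")
  }
  lr <- log10(ratio)
  if (fit$log_y) {
    y0 <- 10^(fit$m * baseline$x0 + fit$b)
    y_hat <- y0 * ratio^(-fit$m)
    lo <- pmin(y0 * ratio^(-fit$ci[1]), y0 * ratio^(-fit$ci[2]))
    hi <- pmax(y0 * ratio^(-fit$ci[1]), y0 * ratio^(-fit$ci[2]))
    mode <- "power_y"
  } else {
    y0 <- fit$m * baseline$x0 + fit$b
    y_hat <- y0 - fit$m * lr
    lo <- pmin(y0 - fit$ci[1] * lr, y0 - fit$ci[2] * lr)
    hi <- pmax(y0 - fit$ci[1] * lr, y0 - fit$ci[2] * lr)
    mode <- "log"
  }
  out <- tibble(ratio = ratio, y_hat = y_hat, ci_low = lo, ci_high = hi)
  out <- new_cb_curve(out, mode, fit, baseline,
                      slope_is_null(fit, 1 - fit$conf_level))
  attr(out, "y0_hat") <- y0
  class(out) <- c("cb_response", setdiff(class(out), "cb_curve"))
  out
}

curve_inputs <- function(fit, at, grid_size, allow_extrapolation) {
  x <- if (is.null(at)) sort(unique(fit$data$x)) else at
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("Evaluation points must be finite numeric.")
  }
  if (!is.null(grid_size)) {
    if (grid_size < 2) abort("`grid_size` must be at least 2.")
    x <- sort(unique(c(x, seq(fit$x_min, fit$x_max, length.out = grid_size))))
  }
  outside <- x < fit$x_min | x > fit$x_max
  if (any(outside)) {
    msg <- paste0(
      "Evaluation point(s) ", paste(format(x[outside]), collapse = ", "),
      " outside the observed x range [", format(fit$x_min), ", ",
      format(fit$x_max), "]; predictions are only supported within the ",
      "range of the data."
    )
    if (allow_extrapolation) warn(paste0("Extrapolating: ", msg)) else abort(msg)
  }
  x
}

new_cb_curve <- function(out, mode, fit, baseline, null_slope) {
  structure(
    out,
    class = c("cb_curve", class(out)),
    mode = mode,
    baseline = baseline,
    m = fit$m,
    ci = fit$ci,
    conf_level = fit$conf_level,
    null_slope = null_slope
  )
}

#' @export
print.cb_curve <- function(x, ...) {
  cat("Relative expression curve (", attr(x, "mode"), "), m = ",
      signif(attr(x, "m"), 4), ", ", format(100 * attr(x, "conf_level")),
      "% slope CI [", signif(attr(x, "ci")[1], 4), ", ",
      signif(attr(x, "ci")[2], 4), "], x0 = ",
      format(attr(x, "baseline")$x0), " (", attr(x, "baseline")$policy,
      ")\n", sep = "")
  if (isTRUE(attr(x, "null_slope"))) {
    cat("Note: slope not distinguishable from 0; no evidence the input",
        "affects expression (R = 1 interpretation applies).\n")
  }
  NextMethod()
}

#' @export
print.cb_response <- function(x, ...) {
  cat("Response curve (", attr(x, "mode"), "), m = ",
      signif(attr(x, "m"), 4), ", baseline response y0 = ",
      signif(attr(x, "y0_hat"), 4), " at x0 = ",
      format(attr(x, "baseline")$x0), "\n", sep = "")
  NextMethod()
}

#' Plot a relative-expression or response curve
#'
#' @param object A `cb_curve` or `cb_response` tibble.
#' @param ... Unused.
#' @return A ggplot: point estimate with confidence ribbon; the baseline
#'   is marked with a dashed line.
#' @export
autoplot.cb_curve <- function(object, ...) {
  xvar <- names(object)[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r_hat), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = xvar, y = "relative expression ratio",
      title = paste0("Relative expression (", attr(object, "mode"), ")"),
      subtitle = paste0("x0 = ", format(attr(object, "baseline")$x0),
                        ", ", format(100 * attr(object, "conf_level")),
                        "% CI from slope interval")
    )
}

#' @rdname autoplot.cb_curve
#' @export
autoplot.cb_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "darkorange", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_hat), colour = "darkorange") +
    ggplot2::geom_hline(yintercept = attr(object, "y0_hat"),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "relative expression ratio", y = "predicted response",
      title = paste0("Predicted response (", attr(object, "mode"), ")")
    )
}
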