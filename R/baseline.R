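#' Choose the baseline value of the independent variable
#'
#' Relative expression ratios are always computed against a fixed baseline
#' input x0, where by construction R(x0) = 1. The choice of x0 does not
#' change the underlying uncertainty (which comes only from the slope),
#' but it decides how that uncertainty maps onto the confidence band:
#' the mean of the observed x gives the smallest, most symmetric bands,
#' which is the recommended default when x was not experimentally
#' manipulated. An extreme value (min or max) or a scientifically
#' meaningful custom value within the observed range can be chosen
#' instead, e.g. an unmanipulated "natural" level of the covariate.
#'
#' @param fit A [fit_ols()] result. Statistics are taken from the raw
#'   (untransformed) x values, so for a log-x fit the baseline is the mean
#'   (or min/max) of the original measurements.
#' @param policy One of `"mean"` (default), `"min"`, `"max"`, `"custom"`.
#' @param value Baseline value when `policy = "custom"`; must lie within
#'   the observed x range (predictions outside the observed range are not
#'   supported).
#' @return An object of class `cb_baseline`: list with `x0` and `policy`.
#' @examples
#' fit <- fit_ols(demo_table(1))
#' choose_baseline(fit)                 # mean: x0 = 9.85
#' choose_baseline(fit, "max")          # x0 = 10.9
#' @export
choose_baseline <- function(fit, policy = c("mean", "min", "max", "custom"),
                            value = NULL) {
  stopifnot(inherits(fit, "cb_fit"))
  policy <- match.arg(policy)
  x0 <- switch(policy,
    mean = mean(fit$data$x),
    min = fit$x_min,
    max = fit$x_max,
    custom = {
      if (is.null(value) || length(value) != 1 || !is.finite(value)) {
        abort("policy = 'custom' needs a single finite `value`.")
      }
      if (value < fit$x_min || value > fit$x_max) {
        abort(paste0(
          "Custom baseline ", format(value), " lies outside the observed ",
          "x range [", format(fit$x_min), ", ", format(fit$x_max), "]; ",
          "predictions are only supported within the range of the data."
        ))
      }
      value
    }
  )
  structure(list(x0 = x0, policy = policy), class = "cb_baseline")
}

#' @export
print.cb_baseline <- function(x, ...) {
  cat("Baseline x0 = ", format(x$x0), " (policy: ", x$policy, ")\n",
      sep = "")
  invisible(x)
}
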