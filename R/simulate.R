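#' Generate synthetic datasets with known parameters
#'
#' Produces datasets matching each analysis case from known ground truth,
#' for property and coverage testing. On the model (possibly transformed)
#' scale the response is always
#' \deqn{y = m x + b + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2)}
#' with covariate values evenly spaced over `x_range` (or `x_grid` as
#' supplied). Per mode:
#'
#' * `"exponential"` (delta-Cq on a raw covariate) and `"response"`
#'   (a response on delta-Cq): emitted as-is.
#' * `"gene"`: same linear model, both axes delta-Cq values.
#' * `"power_x"`: the linear model holds against log10(x); the returned
#'   covariate is on the raw (positive) scale.
#' * `"power_y"`: the linear model holds for log10(y); the returned
#'   response is back-transformed, hence lognormal noise on the raw
#'   scale.
#' * `"ancova"`: one line per group with shared slope `slope` and
#'   intercepts `intercepts`, each group over the same covariate grid.
#'
#' Randomness uses R's default Mersenne-Twister generator; when `seed` is
#' given the stream is isolated with [withr::with_seed()], so the same
#' spec always yields the same dataset and the caller's RNG state is
#' untouched.
#'
#' @param mode One of `"exponential"`, `"response"`, `"gene"`,
#'   `"power_x"`, `"power_y"`, `"ancova"` (or the shorthand letters
#'   A/B/C/D/E used by the command line).
#' @param slope,intercept True slope and intercept on the model scale.
#' @param intercepts Named or unnamed vector of per-group intercepts
#'   (ancova mode; names default to g1, g2, ...).
#' @param noise_sd Residual standard deviation (>= 0) on the model scale.
#' @param n Points per group (>= 3).
#' @param x_range Length-2 range for the covariate (raw scale; must be
#'   positive for `power_x`).
#' @param x_grid Explicit covariate values overriding `x_range`.
#' @param seed Optional integer seed.
#' @return A tibble `(x, y)`, or `(group, x, delta_cq)` for ancova, with
#'   the true parameters attached as attribute `"truth"`.
#' @examples
#' simulate_dataset("exponential", slope = -0.1, noise_sd = 0, n = 5)
#' simulate_dataset("ancova", slope = 0.03,
#'                  intercepts = c(control = 0, treated = -0.287),
#'                  noise_sd = 0.02, n = 8, seed = 1)
#' @export
simulate_dataset <- function(mode = c("exponential", "response", "gene",
                                      "power_x", "power_y", "ancova",
                                      "A", "B", "C", "D", "E"),
                             slope, intercept = 0, intercepts = NULL,
                             noise_sd = 0.05, n = 10,
                             x_range = c(1, 10), x_grid = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("A", "B", "C", "D", "E")) {
    mode <- c(A = "exponential", B = "response", C = "gene",
              D = "power_x", E = "power_y")[[mode]]
  }
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope)) {
    abort("`slope` must be a single finite number.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n < 3) abort("`n` must be at least 3.")
  x <- if (is.null(x_grid)) seq(x_range[1], x_range[2], length.out = n) else x_grid
  gen <- function() {
    if (mode == "ancova") {
      if (is.null(intercepts) || length(intercepts) < 2) {
        abort("ancova mode needs >= 2 `intercepts`.")
      }
      labels <- names(intercepts) %||% paste0("g", seq_along(intercepts))
      if (is.null(names(intercepts))) names(intercepts) <- labels
      purrr::imap(as.list(intercepts), function(b, g) {
        tibble(
          group = g, x = x,
          delta_cq = slope * x + b + rnorm(length(x), 0, noise_sd)
        )
      }) %>% dplyr::bind_rows()
    } else {
      xt <- if (mode == "power_x") {
        if (any(x <= 0)) abort("power_x mode needs positive covariate values.")
        log10(x)
      } else {
        x
      }
      eta <- slope * xt + intercept + rnorm(length(x), 0, noise_sd)
      y <- if (mode == "power_y") 10^eta else eta
      tibble(x = x, y = y)
    }
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "truth") <- list(
    mode = mode, slope = slope, intercept = intercept,
    intercepts = intercepts, noise_sd = noise_sd, seed = seed
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An exactly collinear input is legitimate (se = 0): silence lm's
# advisory about a perfect fit while letting other warnings through.
quiet_perfect <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
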