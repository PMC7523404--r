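#' Per-group regressions of delta-Cq on a covariate
#'
#' First step of the covariance analysis: fit a separate OLS line for each
#' treatment group and check that at least one slope differs from zero.
#' If no slope does, the covariate carries no information and a plain
#' ANOVA on the group means is the appropriate analysis; a message says so.
#'
#' @param data A data frame with a grouping column, a covariate column and
#'   a delta-Cq response column (defaults: first three columns, in that
#'   order, or columns named `group`, `x`, `delta_cq` if present).
#' @param group,x,y Optional unquoted column names.
#' @param conf_level Confidence level for per-group slope intervals.
#' @param alpha Significance level for the any-nonzero-slope check.
#' @return A tibble with one row per group: `group`, `n`, `slope`,
#'   `intercept`, `r2`, `se_slope`, `conf.low`, `conf.high`, `p.value`,
#'   plus a list-column `fit` of [fit_ols()] objects and attribute
#'   `any_slope_nonzero`.
#' @examples
#' fit_group_slopes(demo_table(8))
#' @export
fit_group_slopes <- function(data, group = NULL, x = NULL, y = NULL,
                             conf_level = 0.95, alpha = 0.05) {
  gd <- grouped_columns(data, enquo(group), enquo(x), enquo(y))
  fits <- lapply(split(gd, gd$group), function(d) {
    if (nrow(d) < 3 || length(unique(d$x)) < 2) {
      abort(paste0("Group '", d$group[1],
                   "' needs >= 3 points with >= 2 distinct covariate values."))
    }
    fit_ols(d[, c("x", "y")], conf_level = conf_level)
  })
  out <- purrr::imap(fits, function(f, g) {
    tibble(
      group = g, n = f$n, slope = f$m, intercept = f$b, r2 = f$r2,
      se_slope = f$se_m, conf.low = f$ci[1], conf.high = f$ci[2],
      p.value = f$p_slope
    )
  }) %>% dplyr::bind_rows()
  out$fit <- unname(fits)
  any_nonzero <- any(out$p.value < alpha, na.rm = TRUE)
  if (!any_nonzero) {
    message(
      "No group slope differs from zero at alpha = ", alpha,
      "; the covariate may be ignored and ordinary ANOVA used instead."
    )
  }
  attr(out, "any_slope_nonzero") <- any_nonzero
  out
}

#' Homogeneity-of-slopes (treatment-by-covariate interaction) test
#'
#' ANCOVA requires that the group regression lines be parallel. This is
#' tested with an extra-sum-of-squares F test comparing the full model
#' (separate slope per group, i.e. a treatment x covariate interaction)
#' to the reduced common-slope model:
#' \deqn{F = \frac{(RSS_{red} - RSS_{full}) / (k - 1)}{RSS_{full} / (n - 2k)}}
#' for k groups and n points. A large p-value means the slopes can be
#' treated as equal and ANCOVA may proceed; p below the chosen alpha means
#' the between-group difference varies with the covariate and ANCOVA is
#' not appropriate.
#'
#' @inheritParams fit_group_slopes
#' @return An object of class `cb_homogeneity`: list with `f_stat`,
#'   `df_num` (k - 1), `df_den` (n - 2k), `p_value`.
#' @examples
#' test_slope_homogeneity(demo_table(8)) # p = 0.613: parallel
#' @export
test_slope_homogeneity <- function(data, group = NULL, x = NULL, y = NULL) {
  gd <- grouped_columns(data, enquo(group), enquo(x), enquo(y))
  k <- length(unique(gd$group))
  n <- nrow(gd)
  df_den <- n - 2 * k
  if (df_den < 1) abort("Not enough points for the interaction test (n - 2k < 1).")
  full <- lm(y ~ group * x, data = gd)
  red <- lm(y ~ group + x, data = gd)
  rss_full <- sum(full$residuals^2)
  rss_red <- sum(red$residuals^2)
  df_num <- k - 1
  # Noise-free parallel groups leave both models with ~zero RSS; report
  # F = 0, p = 1 rather than 0/0.
  denom <- rss_full / df_den
  if (denom <= .Machine$double.eps * max(1, sum(gd$y^2)) &&
      (rss_red - rss_full) <= .Machine$double.eps * max(1, sum(gd$y^2))) {
    f_stat <- 0
  } else {
    f_stat <- max(0, (rss_red - rss_full) / df_num / denom)
  }
  p_value <- pf(f_stat, df_num, df_den, lower.tail = FALSE)
  structure(
    list(f_stat = f_stat, df_num = df_num, df_den = df_den,
         p_value = p_value),
    class = "cb_homogeneity"
  )
}

#' @export
print.cb_homogeneity <- function(x, ...) {
  cat("Homogeneity of slopes: F(", x$df_num, ", ", x$df_den, ") = ",
      signif(x$f_stat, 4), ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' One-way ANCOVA with an enforced common slope
#'
#' Refits the general linear model without the treatment-by-covariate
#' interaction, giving every group the same slope and its own intercept:
#' \deqn{\hat y = m x + b_g}
#' The common slope is the pooled \eqn{\sum_g S_{xy,g} / \sum_g S_{xx,g}}.
#' Because the lines are parallel, the vertical distance between any two
#' is constant in x and equals the intercept difference b_i - b_j, which
#' on the delta-Cq scale is a delta-delta-Cq: the basis for the
#' expression-ratio contrasts of [expression_contrasts()].
#'
#' The fit refuses to proceed when the homogeneity-of-slopes test rejects
#' parallelism at `alpha` (classed error `cb_heterogeneous_slopes`
#' carrying the test), unless `force = TRUE`, which attaches a warning
#' instead.
#'
#' @inheritParams fit_group_slopes
#' @param alpha Significance threshold for the homogeneity test (default
#'   0.05).
#' @param force Proceed despite a significant interaction (warning).
#' @return An object of class `cb_ancova`: list with `m_common`,
#'   `intercepts` (named by group), `mse` (residual mean square on
#'   `df_resid` = n - k - 1 degrees of freedom), `group_ns`,
#'   `group_means` (covariate means), `homogeneity`
#'   (a `cb_homogeneity`), `conf_level`, the model and the data.
#' @examples
#' fit <- fit_ancova(demo_table(8))
#' glance(fit)
#' expression_contrasts(fit)
#' @export
fit_ancova <- function(data, group = NULL, x = NULL, y = NULL,
                       conf_level = 0.95, alpha = 0.05, force = FALSE) {
  gd <- grouped_columns(data, enquo(group), enquo(x), enquo(y))
  homog <- test_slope_homogeneity(gd)
  if (homog$p_value < alpha) {
    msg <- paste0(
      "Slopes are heterogeneous (interaction p = ",
      signif(homog$p_value, 4), " < ", alpha,
      "): the group difference varies with the covariate and ANCOVA is ",
      "not appropriate."
    )
    if (!force) {
      abort(msg, class = "cb_heterogeneous_slopes", homogeneity = homog)
    }
    warn(paste0(msg, " Proceeding because force = TRUE."))
  }
  model <- lm(y ~ 0 + group + x, data = gd)
  cf <- coef(model)
  groups <- levels(factor(gd$group))
  intercepts <- setNames(cf[paste0("group", groups)], groups)
  n <- nrow(gd)
  k <- length(groups)
  structure(
    list(
      m_common = unname(cf[["x"]]),
      intercepts = intercepts,
      mse = sum(model$residuals^2) / (n - k - 1),
      df_resid = n - k - 1,
      group_ns = table(gd$group),
      group_means = tapply(gd$x, gd$group, mean),
      homogeneity = homog,
      conf_level = conf_level,
      model = model,
      data = gd
    ),
    class = "cb_ancova"
  )
}

#' @export
print.cb_ancova <- function(x, ...) {
  cat("ANCOVA with common slope m = ", signif(x$m_common, 4),
      " (residual df = ", x$df_resid, ")\n", sep = "")
  cat("Homogeneity of slopes p = ", signif(x$homogeneity$p_value, 4),
      "\n", sep = "")
  cat("Group intercepts:\n")
  print(signif(x$intercepts, 4))
  invisible(x)
}

#' @export
tidy.cb_ancova <- function(x, ...) {
  tibble(
    group = names(x$intercepts),
    intercept = unname(x$intercepts),
    n = as.integer(x$group_ns[names(x$intercepts)]),
    covariate_mean = as.numeric(x$group_means[names(x$intercepts)])
  )
}

#' @export
glance.cb_ancova <- function(x, ...) {
  tibble(
    m_common = x$m_common,
    mse = x$mse,
    df.residual = x$df_resid,
    nobs = nrow(x$data),
    n.groups = length(x$intercepts),
    homogeneity.f = x$homogeneity$f_stat,
    homogeneity.p = x$homogeneity$p_value,
    conf.level = x$conf_level
  )
}

#' Pairwise expression-ratio contrasts from an ANCOVA fit
#'
#' For each pair of groups the intercept difference
#' \eqn{\widehat{\Delta\Delta C_q^{(w)}} = b_i - b_j} of the parallel
#' fitted lines is converted to a relative expression ratio
#' \deqn{\hat R = 10^{-(b_i - b_j)}}
#' with confidence interval \eqn{(10^{-U}, 10^{-L})}, where (L, U) is the
#' t interval for the intercept difference (bounds swap because of the
#' negative exponent). The standard error comes from the model covariance
#' of the intercepts, which reduces to \eqn{\sqrt{mse (1/n_i + 1/n_j)}}
#' when the groups share the same covariate values. R above 1 means group
#' i expresses the gene more highly than group j (its delta-Cq line sits
#' lower).
#'
#' @param fit A [fit_ancova()] result.
#' @param pairs Optional list of 2-vectors `c(group_i, group_j)`; default
#'   is every unordered pair in group order.
#' @param conf_level Confidence level; defaults to the fit's.
#' @param adjustment Multiplicity adjustment: `"none"` (default;
#'   unadjusted Fisher-LSD-style t intervals), `"bonferroni"` or
#'   `"sidak"`, applied over the number of requested pairs to both
#'   p-values and interval levels. Tukey HSD is not offered (it needs
#'   studentized-range quantiles and is out of scope).
#' @return A tibble of class `cb_contrasts`: one row per pair with
#'   `group_i`, `group_j`, `diff` (b_i - b_j), `se`, `ci_low`, `ci_high`,
#'   `statistic`, `p.value`, `r_hat`, `r_ci_low`, `r_ci_high`,
#'   `adjustment`.
#' @examples
#' fit <- fit_ancova(demo_table(8))
#' expression_contrasts(fit)
#' @export
expression_contrasts <- function(fit, pairs = NULL,
                                 conf_level = fit$conf_level,
                                 adjustment = c("none", "bonferroni", "sidak")) {
  stopifnot(inherits(fit, "cb_ancova"))
  adjustment <- match.arg(adjustment)
  groups <- names(fit$intercepts)
  if (is.null(pairs)) {
    # later group vs earlier group, so treatments contrast against the
    # first (control) level: (g2, g1), (g3, g1), (g3, g2)
    pairs <- lapply(combn(groups, 2, simplify = FALSE), rev)
  }
  m <- length(pairs)
  alpha <- 1 - conf_level
  alpha_adj <- switch(adjustment,
    none = alpha,
    bonferroni = alpha / m,
    sidak = 1 - (1 - alpha)^(1 / m)
  )
  rows <- purrr::map(pairs, function(p) {
    ct <- contrast_stats(fit, p[1], p[2], alpha_adj)
    ct$p.value <- switch(adjustment,
      none = ct$p_raw,
      bonferroni = min(1, ct$p_raw * m),
      sidak = 1 - (1 - ct$p_raw)^m
    )
    tibble(
      group_i = p[1], group_j = p[2], diff = ct$diff, se = ct$se,
      ci_low = ct$ci[1], ci_high = ct$ci[2], statistic = ct$stat,
      p.value = ct$p.value,
      r_hat = 10^(-ct$diff),
      r_ci_low = 10^(-ct$ci[2]), r_ci_high = 10^(-ct$ci[1]),
      adjustment = adjustment
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cb_contrasts", class(out)),
            conf_level = conf_level, df = fit$df_resid)
}

contrast_stats <- function(fit, gi, gj, alpha) {
  groups <- names(fit$intercepts)
  if (!gi %in% groups || !gj %in% groups) {
    abort(paste0("Unknown group label: ",
                 paste(setdiff(c(gi, gj), groups), collapse = ", "), "."))
  }
  if (identical(gi, gj)) {
    return(list(diff = 0, se = 0, ci = c(0, 0), stat = NA_real_,
                p_raw = 1))
  }
  V <- quiet_perfect(vcov(fit$model))
  ti <- paste0("group", gi)
  tj <- paste0("group", gj)
  d <- fit$intercepts[[gi]] - fit$intercepts[[gj]]
  se <- sqrt(V[ti, ti] + V[tj, tj] - 2 * V[ti, tj])
  tq <- qt(1 - alpha / 2, fit$df_resid)
  stat <- d / se
  list(
    diff = d, se = se, ci = c(d - tq * se, d + tq * se), stat = stat,
    p_raw = 2 * pt(-abs(stat), fit$df_resid)
  )
}

#' Plot an ANCOVA fit: data and parallel regression lines
#'
#' @param object A `cb_ancova` fit.
#' @param ... Unused.
#' @return A ggplot of delta-Cq against the covariate, coloured by group,
#'   with the common-slope fitted line for each group.
#' @export
autoplot.cb_ancova <- function(object, ...) {
  lines <- tibble(
    group = names(object$intercepts),
    intercept = unname(object$intercepts),
    slope = object$m_common
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$group)
    ) +
    ggplot2::labs(
      x = "covariate", y = "weighted delta-Cq",
      title = paste0("ANCOVA, common slope m = ",
                     signif(object$m_common, 3))
    )
}

grouped_columns <- function(data, gq, xq, yq) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  default_names <- c("group", "x", "delta_cq")
  if (quo_is_null(gq) && all(default_names %in% names(data))) {
    gd <- tibble(group = data$group, x = data$x, y = data$delta_cq)
  } else {
    gv <- if (quo_is_null(gq)) data[[1]] else eval_tidy(gq, data)
    xv <- if (quo_is_null(xq)) data[[2]] else eval_tidy(xq, data)
    yv <- if (quo_is_null(yq)) data[[3]] else eval_tidy(yq, data)
    gd <- tibble(group = as.character(gv), x = xv, y = yv)
  }
  if (!is.numeric(gd$x) || !is.numeric(gd$y)) {
    abort("Covariate and response columns must be numeric.")
  }
  if (anyNA(gd)) abort("Missing values in grouped data.")
  if (length(unique(gd$group)) < 2) {
    abort("At least 2 groups are required for ANCOVA.")
  }
  counts <- table(gd$group)
  if (any(counts < 3)) {
    abort(paste0("Each group needs >= 3 points; too few in: ",
                 paste(names(counts)[counts < 3], collapse = ", "), "."))
  }
  gd
}
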