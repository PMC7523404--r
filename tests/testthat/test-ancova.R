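diet <- demo_table(8)

test_that("per-group regressions recover each diet's slope", {
  gs <- fit_group_slopes(diet)
  expect_equal(nrow(gs), 3)
  expect_equal(gs$n, rep(8L, 3))
  ctrl <- gs[gs$group == "control", ]
  # hand computation from the printed values: Sxy/Sxx = 5.755/168
  expect_equal(ctrl$slope, 5.755 / 168, tolerance = 1e-6)
  expect_true(attr(gs, "any_slope_nonzero"))
  # per-group fits agree with the normal-equations oracle
  for (g in unique(diet$group)) {
    sub <- diet[diet$group == g, ]
    o <- oracle_ols(sub$x, sub$delta_cq)
    expect_equal(gs$slope[gs$group == g], o$m, tolerance = 1e-9)
    expect_equal(gs$intercept[gs$group == g], o$b, tolerance = 1e-9)
  }
})

test_that("a flat dataset recommends plain ANOVA", {
  flat <- simulate_dataset("ancova", slope = 0,
                           intercepts = c(a = 0.3, b = 0.5),
                           noise_sd = 0.4, n = 6, x_grid = 1:6, seed = 3)
  expect_message(gs <- fit_group_slopes(flat), "ordinary ANOVA")
  expect_false(attr(gs, "any_slope_nonzero"))
  expect_error(fit_group_slopes(diet[diet$group == "control", ]),
               "At least 2 groups")
})

test_that("homogeneity-of-slopes test matches the printed p-value and the oracle", {
  ht <- test_slope_homogeneity(diet)
  expect_equal(ht$p_value, 0.613, tolerance = 0.01 / 0.613)
  expect_equal(ht$df_num, 2)
  expect_equal(ht$df_den, 18)
  o <- oracle_homogeneity(diet$group, diet$x, diet$delta_cq)
  expect_equal(ht$f_stat, o$f, tolerance = 1e-9)
  expect_equal(ht$p_value, o$p, tolerance = 1e-9)
})

test_that("noise-free parallel groups give F = 0, p = 1", {
  par3 <- simulate_dataset("ancova", slope = 0.5,
                           intercepts = c(a = 0, b = 1, c = -1),
                           noise_sd = 0, n = 5, x_grid = 1:5)
  ht <- test_slope_homogeneity(par3)
  expect_identical(ht$f_stat, 0)
  expect_identical(ht$p_value, 1)
})

test_that("grossly different slopes are detected", {
  cross <- withr::with_seed(17, dplyr::bind_rows(
    tibble::tibble(group = "up", x = 1:8,
                   delta_cq = 1 * (1:8) + rnorm(8, 0, 0.01)),
    tibble::tibble(group = "down", x = 1:8,
                   delta_cq = -1 * (1:8) + rnorm(8, 0, 0.01))
  ))
  ht <- test_slope_homogeneity(cross)
  expect_lt(ht$p_value, 0.001)
  o <- oracle_homogeneity(cross$group, cross$x, cross$delta_cq)
  expect_equal(ht$f_stat, o$f, tolerance = 1e-9)
  # and the common-slope fit refuses, carrying the test, unless forced
  err <- expect_error(fit_ancova(cross), class = "cb_heterogeneous_slopes")
  expect_s3_class(err$homogeneity, "cb_homogeneity")
  expect_warning(forced <- fit_ancova(cross, force = TRUE), "force = TRUE")
  expect_s3_class(forced, "cb_ancova")
})

test_that("common-slope fit reproduces printed estimates and pooling identity", {
  fit <- fit_ancova(diet)
  expect_equal(fit$m_common, 0.033, tolerance = 0.001 / 0.033)
  expect_equal(fit$df_resid, 20)
  d_t1c <- fit$intercepts[["treatment1"]] - fit$intercepts[["control"]]
  expect_equal(d_t1c, -0.2873, tolerance = 0.001 / 0.2873)
  # pooled Sxy/Sxx identity, i.e. the Sxx-weighted mean of group slopes
  o <- oracle_homogeneity(diet$group, diet$x, diet$delta_cq)
  expect_equal(fit$m_common, o$m_common, tolerance = 1e-12)
  # residual sums of squares match a brute-force design-matrix solve
  expect_equal(sum(fit$model$residuals^2), o$rss_red, tolerance = 1e-9)
})

test_that("model RSS matches the oracle on subsets of the diet data", {
  for (keep in list(1:6, c(1:4, 6:8), 2:8)) {
    sub <- dplyr::bind_rows(lapply(split(diet, diet$group),
                                   function(d) d[keep, ]))
    ht <- test_slope_homogeneity(sub)
    o <- oracle_homogeneity(sub$group, sub$x, sub$delta_cq)
    expect_equal(ht$f_stat, o$f, tolerance = 1e-9)
    fit <- fit_ancova(sub, alpha = 0)
    expect_equal(fit$m_common, o$m_common, tolerance = 1e-12)
    expect_equal(sum(fit$model$residuals^2), o$rss_red, tolerance = 1e-9)
  }
})

test_that("contrasts reproduce the printed ratios, intervals and p-values", {
  fit <- fit_ancova(diet)
  ct <- expression_contrasts(fit)
  t1c <- ct[ct$group_i == "treatment1" & ct$group_j == "control", ]
  expect_equal(t1c$diff, -0.2873, tolerance = 0.001 / 0.2873)
  expect_equal(t1c$ci_low, -0.3159, tolerance = 0.001 / 0.3159)
  expect_equal(t1c$ci_high, -0.2586, tolerance = 0.001 / 0.2586)
  expect_equal(t1c$r_hat, 1.938, tolerance = 0.005 / 1.938)
  expect_equal(t1c$r_ci_low, 1.81, tolerance = 0.005)
  expect_equal(t1c$r_ci_high, 2.07, tolerance = 0.005)
  expect_lt(t1c$p.value, 0.001)
  t2t1 <- expression_contrasts(
    fit, pairs = list(c("treatment2", "treatment1")))
  expect_equal(t2t1$r_hat, 0.993, tolerance = 0.005 / 0.993)
  expect_equal(t2t1$r_ci_low, 0.930, tolerance = 0.005 / 0.930)
  expect_equal(t2t1$r_ci_high, 1.061, tolerance = 0.005 / 1.061)
  expect_equal(t2t1$p.value, 0.829, tolerance = 0.01 / 0.829)
  t2c <- ct[ct$group_i == "treatment2" & ct$group_j == "control", ]
  expect_equal(t2c$r_hat, 1.924, tolerance = 0.005 / 1.924)
})

test_that("contrasts are antisymmetric and self-contrasts collapse", {
  fit <- fit_ancova(diet)
  ij <- expression_contrasts(fit, pairs = list(c("treatment1", "control")))
  ji <- expression_contrasts(fit, pairs = list(c("control", "treatment1")))
  expect_equal(ij$diff, -ji$diff, tolerance = 1e-12)
  expect_equal(ij$r_hat * ji$r_hat, 1, tolerance = 1e-12)
  expect_equal(ij$p.value, ji$p.value, tolerance = 1e-12)
  self <- expression_contrasts(fit, pairs = list(c("control", "control")))
  expect_identical(self$diff, 0)
  expect_identical(self$r_hat, 1)
  expect_error(expression_contrasts(fit, pairs = list(c("control", "zzz"))),
               "Unknown group")
})

test_that("parallel fitted lines keep a constant vertical separation", {
  fit <- fit_ancova(diet)
  xs <- seq(22, 36, by = 2)
  line <- function(g) fit$m_common * xs + fit$intercepts[[g]]
  gap <- line("treatment1") - line("control")
  expect_equal(gap, rep(gap[1], length(xs)), tolerance = 1e-12)
  expect_equal(gap[1],
               fit$intercepts[["treatment1"]] - fit$intercepts[["control"]])
})

test_that("contrast intervals agree with adjusted means from emmeans", {
  skip_if_not_installed("emmeans")
  fit <- fit_ancova(diet)
  ref <- lm(delta_cq ~ group + x, data = diet)
  em <- emmeans::emmeans(ref, "group")
  pw <- as.data.frame(emmeans::contrast(em, method = "revpairwise",
                                        adjust = "none",
                                        infer = c(TRUE, TRUE)))
  t1c <- pw[pw$contrast == "treatment1 - control", ]
  ours <- expression_contrasts(fit,
                               pairs = list(c("treatment1", "control")))
  expect_equal(ours$diff, t1c$estimate, tolerance = 1e-10)
  expect_equal(ours$ci_low, t1c$lower.CL, tolerance = 1e-10)
  expect_equal(ours$ci_high, t1c$upper.CL, tolerance = 1e-10)
  expect_equal(ours$p.value, t1c$p.value, tolerance = 1e-10)
})

test_that("multiplicity adjustments widen intervals and inflate p-values", {
  fit <- fit_ancova(diet)
  none <- expression_contrasts(fit)
  bonf <- expression_contrasts(fit, adjustment = "bonferroni")
  sidak <- expression_contrasts(fit, adjustment = "sidak")
  expect_true(all(bonf$ci_high - bonf$ci_low > none$ci_high - none$ci_low))
  expect_true(all(sidak$ci_high - sidak$ci_low > none$ci_high - none$ci_low))
  expect_true(all(bonf$p.value >= none$p.value))
  expect_true(all(sidak$p.value >= none$p.value))
  expect_true(all(bonf$ci_high - bonf$ci_low >=
                    sidak$ci_high - sidak$ci_low))
})

test_that("contrast intervals cover a known intercept offset", {
  offset <- -0.287
  hits <- withr::with_seed(99, {
    vapply(1:400, function(i) {
      d <- simulate_dataset("ancova", slope = 0.033,
                            intercepts = c(c = 0, t = offset),
                            noise_sd = 0.05, n = 8,
                            x_grid = seq(22, 36, by = 2))
      fit <- fit_ancova(d, alpha = 1e-9) # never refuse during simulation
      ct <- expression_contrasts(fit, pairs = list(c("t", "c")))
      ct$ci_low <= offset && offset <= ct$ci_high
    }, logical(1))
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.035 / 0.95)
})

test_that("ancova accessors and plot behave", {
  fit <- fit_ancova(diet)
  td <- tidy(fit)
  expect_named(td, c("group", "intercept", "n", "covariate_mean"))
  expect_equal(td$covariate_mean, rep(29, 3))
  gl <- glance(fit)
  expect_equal(gl$m_common, fit$m_common)
  expect_equal(gl$nobs, 24)
  p <- ggplot2::ggplot_build(autoplot(fit))
  expect_s3_class(p$plot, "ggplot")
})
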