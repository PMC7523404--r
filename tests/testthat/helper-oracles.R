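# Independent oracles: deliberately naive implementations used only to
# cross-check the package, never sharing code with it.

# OLS by explicit normal equations on the design matrix [1, x].
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  b <- beta[1]
  m <- beta[2]
  res <- y - X %*% beta
  n <- length(y)
  rss <- sum(res^2)
  sxx <- sum((x - mean(x))^2)
  se_m <- sqrt(rss / (n - 2) / sxx)
  tss <- sum((y - mean(y))^2)
  list(m = m, b = b, r2 = 1 - rss / tss, se_m = se_m, rss = rss)
}

# RSS at a given slope with the intercept profiled out analytically.
oracle_rss_at_slope <- function(x, y, m) {
  b <- mean(y) - m * mean(x)
  sum((y - m * x - b)^2)
}

# Slope t interval computed from first principles.
oracle_slope_ci <- function(x, y, level = 0.95) {
  o <- oracle_ols(x, y)
  tq <- qt(1 - (1 - level) / 2, length(x) - 2)
  c(o$m - tq * o$se_m, o$m + tq * o$se_m)
}

# Extra-sum-of-squares F test between separate-slopes and common-slope
# models, built from per-group sums of squares only.
oracle_homogeneity <- function(group, x, y) {
  groups <- unique(group)
  k <- length(groups)
  n <- length(y)
  rss_full <- sum(vapply(groups, function(g) {
    i <- group == g
    oracle_ols(x[i], y[i])$rss
  }, numeric(1)))
  # common slope: pooled Sxy / Sxx, per-group intercepts
  sxy <- sum(vapply(groups, function(g) {
    i <- group == g
    sum((x[i] - mean(x[i])) * (y[i] - mean(y[i])))
  }, numeric(1)))
  sxx <- sum(vapply(groups, function(g) {
    i <- group == g
    sum((x[i] - mean(x[i]))^2)
  }, numeric(1)))
  m <- sxy / sxx
  rss_red <- sum(vapply(groups, function(g) {
    i <- group == g
    b <- mean(y[i]) - m * mean(x[i])
    sum((y[i] - m * x[i] - b)^2)
  }, numeric(1)))
  f <- ((rss_red - rss_full) / (k - 1)) / (rss_full / (n - 2 * k))
  list(f = f, p = pf(f, k - 1, n - 2 * k, lower.tail = FALSE),
       m_common = m, rss_red = rss_red, rss_full = rss_full)
}

# Signatures pinning the embedded example tables: any edit to the stored
# inputs fails the suite.
demo_table_signature <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  c(nrow(tab), round(unname(colSums(tab[num])), 6))
}
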