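test_that("pearson correlation matches the direct covariance formula", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3)
  y <- c(2.0, 3.1, 2.5, 6.0, 3.9, 1.1)
  ct <- pearson_cor(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_oracle, tolerance = 1e-12)
  expect_equal(ct$t_stat, r_oracle * sqrt(4 / (1 - r_oracle^2)),
               tolerance = 1e-12)
  expect_equal(ct$p_value, 2 * pt(-abs(ct$t_stat), 4), tolerance = 1e-12)
  expect_equal(pearson_cor(1:10, 1:10 * 2 + 1)$r, 1)
  # orthogonal contrast over symmetric x
  expect_equal(pearson_cor(c(-2, -1, 0, 1, 2), c(2, -1, -2, -1, 2))$r, 0)
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_cor(c(1, 2, NA, 4), 1:4), "finite")
})

test_that("point-biserial equals pearson on the 0/1 coding and the textbook form", {
  g <- c(0, 0, 0, 1, 1, 1)
  y <- c(3.2, 4.1, 3.6, 5.0, 4.2, 4.9)
  pb <- point_biserial(g, y)
  expect_identical(pb$kind, "point_biserial")
  expect_equal(pb$r, pearson_cor(g, y)$r, tolerance = 1e-15)
  # textbook mean-difference formula: (M1 - M0)/s_y * sqrt(p q n/(n-1))
  n <- length(y); p1 <- mean(g)
  r_md <- (mean(y[g == 1]) - mean(y[g == 0])) / sd(y) *
    sqrt(p1 * (1 - p1) * n / (n - 1))
  expect_equal(pb$r, r_md, tolerance = 1e-12)
  expect_equal(point_biserial(c(0, 0, 1, 1), c(2, 4, 2, 4))$r, 0)
  expect_error(point_biserial(c(0, 0, 0), 1:3), "both groups")
  expect_error(point_biserial(c(0, 1, 2), 1:3), "0 or 1")
})

test_that("mixed ANOVA degenerate constructions give zero F where expected", {
  g <- rep(c("a", "b"), each = 5)
  deep <- c(rnorm(5, 4), rnorm(5, 3))
  a0 <- mixed_anova_2x2(g, deep, deep)        # identical columns: D = 0
  expect_equal(a0["within_main", "F"], 0)
  expect_equal(a0["within_main", "eta_p2"], 0)
  expect_equal(a0["interaction", "F"], 0)
  # identical D distributions, shifted averages: interaction 0, between > 0
  d1 <- c(1, 2, 3, 2, 1)
  deep2 <- c(3 + d1, 6 + d1); surf2 <- c(rep(3, 5), rep(6, 5))
  a1 <- mixed_anova_2x2(g, deep2, surf2)
  expect_equal(a1["interaction", "F"], 0)
  expect_gt(a1["between_main", "F"], 0)
  expect_error(mixed_anova_2x2(rep("a", 4), 1:4, 2:5), "two groups")
  expect_error(mixed_anova_2x2(c("a", "a", "a", "b"), 1:4, c(2, 1, 4, 3)),
               "at least 2")
})

test_that("mixed ANOVA matches the cell-means decomposition on a fixed balanced design", {
  g <- rep(c("abs", "ex"), each = 4)
  deep <- c(4.2, 3.8, 4.6, 4.0, 3.1, 3.5, 2.9, 3.3)
  surf <- c(2.0, 2.6, 2.2, 2.8, 3.0, 3.4, 2.8, 3.6)
  a <- mixed_anova_2x2(g, deep, surf)
  o <- oracle_mixed_anova(g, deep, surf)
  expect_equal(a["within_main", "F"], o$within, tolerance = 1e-9)
  expect_equal(a["between_main", "F"], o$between, tolerance = 1e-9)
  expect_equal(a["interaction", "F"], o$interaction, tolerance = 1e-9)
  expect_equal(a$df2, rep(6L, 3))
  expect_equal(a$eta_p2, a$F / (a$F + a$df2))
})

test_that("mixed ANOVA agrees with car's Type-III repeated-measures tests on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(77)
  g <- c(rep("abs", 14), rep("ex", 9))
  deep <- rnorm(23, ifelse(g == "abs", 4, 3.4), 0.7)
  surf <- rnorm(23, 2.8, 0.7)
  a <- mixed_anova_2x2(g, deep, surf)
  # Type III requires sum-to-zero coding of the between factor
  mod <- stats::lm(cbind(deep, surf) ~ g,
                   contrasts = list(g = "contr.sum"))
  idata <- data.frame(scale = factor(c("deep", "surface")))
  ca <- suppressWarnings(summary(
    car::Anova(mod, idata = idata, idesign = ~scale, type = 3),
    multivariate = FALSE))$univariate.tests
  expect_equal(a["between_main", "F"], unname(ca["g", "F value"]),
               tolerance = 1e-8)
  expect_equal(a["within_main", "F"], unname(ca["scale", "F value"]),
               tolerance = 1e-8)
  expect_equal(a["interaction", "F"], unname(ca["g:scale", "F value"]),
               tolerance = 1e-8)
})

test_that("swapping the within-condition labels leaves the interaction F unchanged", {
  set.seed(3)
  g <- rep(c("a", "b"), c(6, 8))
  deep <- rnorm(14, 4); surf <- rnorm(14, 3)
  a <- mixed_anova_2x2(g, deep, surf)
  b <- mixed_anova_2x2(g, surf, deep)
  expect_equal(b["interaction", "F"], a["interaction", "F"])
  expect_equal(b["within_main", "F"], a["within_main", "F"])
  expect_equal(b["between_main", "F"], a["between_main", "F"])
})

test_that("partial eta squared reproduces every reported effect at 3 decimals", {
  reported <- rbind(
    c(53.47, 80, 0.401), c(5.56, 80, 0.065), c(0.68, 80, 0.008),
    c(33.88, 59, 0.365), c(0.20, 59, 0.003), c(0.30, 59, 0.005),
    c(87.05, 141, 0.382), c(2.96, 141, 0.021), c(0.02, 141, 0.000),
    c(7.34, 111, 0.062), c(0.86, 111, 0.008), c(0.43, 111, 0.004))
  expect_equal(round(partial_eta_sq(reported[, 1], 1, reported[, 2]), 3),
               reported[, 3])
  expect_equal(partial_eta_sq(0, 1, 100), 0)
})

test_that("the BIC procedure reproduces the four reported null posteriors", {
  expect_equal(round(bic_posterior_null(0.68, 1, 80, 82)$p_h0, 3), 0.865)
  expect_equal(round(bic_posterior_null(0.30, 1, 59, 61)$p_h0, 3), 0.870)
  expect_equal(round(bic_posterior_null(0.02, 1, 141, 143)$p_h0, 3), 0.922)
  expect_equal(round(bic_posterior_null(0.43, 1, 111, 113)$p_h0, 3), 0.895)
  # F = 0 closed form: BF01 = sqrt(n)
  b0 <- bic_posterior_null(0, 1, 141, 143)
  expect_equal(b0$p_h0, sqrt(143) / (1 + sqrt(143)))
  expect_equal(b0$bf01, sqrt(143))
  expect_error(bic_posterior_null(-1, 1, 80, 82))
})

test_that("correlation power reproduces the reported integer percentages", {
  expect_identical(correlation_power(0.3, 82)$percent, 79)
  expect_identical(correlation_power(0.3, 113)$percent, 90)
  expect_identical(correlation_power(0.3, 61)$percent, 66)
  expect_identical(correlation_power(0.3, 143)$percent, 96)
  # at rho = 0 the power equals the size of the test (Fisher-z approximation)
  for (n in c(30, 82, 200))
    expect_lt(abs(correlation_power(0, n)$power - 0.05), 5e-3)
  expect_gt(correlation_power(0.5, 82)$power, correlation_power(0.3, 82)$power)
})

test_that("noncentral-F power matches the Poisson-mixture quadrature oracle", {
  p0 <- f_test_power(0, 1, 100)
  expect_equal(p0$power, 0.05)   # null effect: power = alpha
  pw <- f_test_power(0.25, 1, 128)
  crit <- qf(0.95, 1, 126)
  expect_equal(pw$power, oracle_ncf_tail(crit, 1, 126, 0.25^2 * 128),
               tolerance = 1e-6)
  powers <- vapply(c(50, 100, 200), function(n)
    f_test_power(0.25, 1, n)$power, 0)
  expect_true(all(diff(powers) > 0))
})
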