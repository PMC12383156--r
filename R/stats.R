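#' Pearson product-moment correlation with t test
#'
#' Thin structured wrapper around [stats::cor.test()] returning the
#' quantities reported in the analysis tables.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, each with
#'   nonzero variance.
#' @return An object of class `cb_cor`: `r`, `n`, `t_stat`, `p_value`,
#'   `kind`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pearson_cor: inputs must be finite (drop missing values first)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_cor: zero variance input, correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = n,
                 t_stat = unname(ct$statistic),
                 p_value = ct$p.value, kind = "pearson"),
            class = "cb_cor")
}

#' Point-biserial correlation (0/1 group coding vs a continuous variable)
#'
#' Defined as the Pearson correlation applied to the dichotomous 0/1
#' coding; in the study convention abstraction learners are coded 0 and
#' exemplar learners 1.
#'
#' @param group01 Vector of 0/1 codes; both groups must be represented.
#' @param y Continuous variable.
#' @return A `cb_cor` with `kind = "point_biserial"`.
#' @export
point_biserial <- function(group01, y) {
  g <- as.numeric(group01)
  if (!all(g %in% c(0, 1)))
    stop("point_biserial: group codes must be 0 or 1")
  if (length(unique(g)) < 2L)
    stop("point_biserial: both groups must be present")
  out <- pearson_cor(g, y)
  out$kind <- "point_biserial"
  out
}

#' @export
print.cb_cor <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, t = %.3f, n = %d, p = %.4g\n",
              x$kind, x$r, x$t_stat, x$n, x$p_value))
  invisible(x)
}

#' 2 x 2 mixed-design ANOVA (one between, one within factor)
#'
#' For a design with a two-level between-subjects factor (learner group)
#' and a two-level within-subjects factor (deep vs surface scale score),
#' all three effects reduce to single-df contrasts on the per-subject
#' difference `D = deep - surface` and average `A = (deep + surface)/2`:
#' the interaction is the two-group comparison of `D`, the between-groups
#' main effect is the two-group comparison of `A`, and the within-subjects
#' main effect tests the *unweighted* mean of the two group means of `D`
#' against zero (the Type-III convention, which matches standard GLM
#' output under unequal group sizes).  Each F has df (1, n1 + n2 - 2) and
#' partial eta squared F/(F + df2).
#'
#' @param group Two-level factor (or coercible) of group membership.
#' @param deep,surface Paired per-subject scores.
#' @return Object of class `cb_anova`: a data frame with rows
#'   `within_main`, `between_main`, `interaction` and columns `effect`,
#'   `F`, `df1`, `df2`, `p_value`, `eta_p2`.
#' @examples
#' g <- rep(c("abs", "ex"), each = 4)
#' mixed_anova_2x2(g, deep = c(4, 5, 4, 5, 3, 4, 3, 4),
#'                 surface = c(2, 3, 2, 3, 3, 4, 3, 4))
#' @export
mixed_anova_2x2 <- function(group, deep, surface) {
  g <- factor(group)
  n <- length(g)
  stopifnot(length(deep) == n, length(surface) == n)
  if (nlevels(g) != 2L)
    stop("mixed_anova_2x2: exactly two groups required")
  if (any(is.na(deep)) || any(is.na(surface)) || any(is.na(g)))
    stop("mixed_anova_2x2: missing values not allowed")
  i1 <- g == levels(g)[1L]
  n1 <- sum(i1); n2 <- n - n1
  if (n1 < 2L || n2 < 2L)
    stop("mixed_anova_2x2: each group needs at least 2 subjects")
  D <- deep - surface
  A <- (deep + surface) / 2
  df2 <- n1 + n2 - 2L
  cfac <- 1 / n1 + 1 / n2
  pooled_var <- function(y) {
    (sum((y[i1] - mean(y[i1]))^2) + sum((y[!i1] - mean(y[!i1]))^2)) / df2
  }
  fstat <- function(num, s2, c) {
    if (num == 0) 0 else if (s2 == 0) Inf else num^2 / (s2 * c)
  }
  s2D <- pooled_var(D); s2A <- pooled_var(A)
  Fs <- c(
    within_main = fstat((mean(D[i1]) + mean(D[!i1])) / 2, s2D, cfac / 4),
    between_main = fstat(mean(A[i1]) - mean(A[!i1]), s2A, cfac),
    interaction = fstat(mean(D[i1]) - mean(D[!i1]), s2D, cfac))
  out <- data.frame(effect = names(Fs), F = unname(Fs), df1 = 1L, df2 = df2,
                    p_value = stats::pf(unname(Fs), 1, df2, lower.tail = FALSE),
                    eta_p2 = partial_eta_sq(unname(Fs), 1, df2),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$effect
  class(out) <- c("cb_anova", "data.frame")
  out
}

#' @export
print.cb_anova <- function(x, ...) {
  cat("2 x 2 mixed-design ANOVA\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 2); df$p_value <- signif(df$p_value, 3)
  df$eta_p2 <- round(df$eta_p2, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Partial eta squared from an F ratio
#'
#' `eta_p2 = F * df1 / (F * df1 + df2)`.  Conventional benchmarks: 0.01
#' small, 0.06 medium, 0.14 large.
#'
#' @param F,df1,df2 F ratio and its degrees of freedom (vectorised).
#' @return Partial eta squared in \[0, 1\].
#' @examples
#' partial_eta_sq(53.47, 1, 80)  # 0.401
#' @export
partial_eta_sq <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 >= 1), all(df2 >= 1))
  F * df1 / (F * df1 + df2)
}

#' Posterior probability of the null from the BIC approximation
#'
#' Converts an ANOVA F ratio into a Bayes factor favouring the null via
#' the BIC difference between the null and alternative models:
#' `SSE1/SSE0 = 1 / (1 + F * df1 / df2)`,
#' `dBIC10 = n * log(SSE1/SSE0) + df1 * log(n)`,
#' `BF01 = exp(dBIC10 / 2)`, and the posterior (with equal prior odds)
#' `pH0 = BF01 / (1 + BF01)`.  `n` is the number of participants.
#'
#' @param F F ratio of the tested effect (>= 0).
#' @param df1,df2 Its degrees of freedom.
#' @param n Number of participants contributing to the model (> df1).
#' @return Object of class `cb_bayes`: `delta_bic`, `bf01`, `p_h0`,
#'   `n_used`.
#' @examples
#' bic_posterior_null(0.68, 1, 80, 82)$p_h0  # 0.865
#' @export
bic_posterior_null <- function(F, df1, df2, n) {
  stopifnot(F >= 0, df1 >= 1, df2 >= 1, n > df1)
  sse_ratio <- 1 / (1 + F * df1 / df2)
  dbic <- n * log(sse_ratio) + df1 * log(n)
  bf01 <- exp(dbic / 2)
  structure(list(delta_bic = dbic, bf01 = bf01,
                 p_h0 = bf01 / (1 + bf01), n_used = n),
            class = "cb_bayes")
}

#' @export
print.cb_bayes <- function(x, ...) {
  cat(sprintf("BIC null posterior: dBIC10 = %.3f, BF01 = %.3f, p(H0|data) = %.3f (n = %d)\n",
              x$delta_bic, x$bf01, x$p_h0, x$n_used))
  invisible(x)
}

#' Power of the test of zero correlation
#'
#' Power to detect a population correlation `rho` with the two-sided
#' alpha-level t test of r = 0, computed the way G*Power's exact
#' correlation module is conventionally approximated: the critical r is
#' taken from the t distribution with df = n - 2, and the sampling
#' distribution of the Fisher-z transformed r under rho is normal with
#' bias-corrected mean `atanh(rho) + rho / (2 (n - 1))` and SD
#' `1 / sqrt(n - 3)`.
#'
#' @param rho Population correlation, |rho| < 1.
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @param two_sided Two-sided test? Default TRUE.
#' @return Object of class `cb_power`: `test`, `effect_size`, `n`,
#'   `alpha`, `power` (raw) and `percent` (rounded to integer percent, the
#'   precision at which such power figures are reported).
#' @examples
#' correlation_power(0.3, 82)$percent  # 79
#' @export
correlation_power <- function(rho, n, alpha = 0.05, two_sided = TRUE) {
  stopifnot(abs(rho) < 1, n >= 4)
  a <- if (two_sided) alpha / 2 else alpha
  tcrit <- stats::qt(1 - a, n - 2)
  rcrit <- tcrit / sqrt(tcrit^2 + n - 2)
  zcrit <- atanh(rcrit)
  mu <- atanh(rho) + rho / (2 * (n - 1))
  s <- 1 / sqrt(n - 3)
  power <- stats::pnorm((mu - zcrit) / s) +
    if (two_sided) stats::pnorm((-zcrit - mu) / s) else 0
  structure(list(test = "correlation", effect_size = rho, n = n,
                 alpha = alpha, power = power,
                 percent = round(100 * power)),
            class = "cb_power")
}

#' Power of a fixed-effects F test (noncentral F)
#'
#' Generic noncentral-F power utility with noncentrality
#' `lambda = f^2 * n_total` (Cohen's f) and error df
#' `n_total - df1 - 1`.
#'
#' @param cohen_f Cohen's f effect size (>= 0).
#' @param df1 Numerator degrees of freedom.
#' @param n_total Total sample size.
#' @param alpha Significance level.
#' @return A `cb_power` object.
#' @export
f_test_power <- function(cohen_f, df1, n_total, alpha = 0.05) {
  stopifnot(cohen_f >= 0, df1 >= 1, n_total > df1 + 1)
  df2 <- n_total - df1 - 1
  lambda <- cohen_f^2 * n_total
  fcrit <- stats::qf(1 - alpha, df1, df2)
  power <- stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
  structure(list(test = "f_test", effect_size = cohen_f, n = n_total,
                 alpha = alpha, power = power,
                 percent = round(100 * power)),
            class = "cb_power")
}

#' @export
print.cb_power <- function(x, ...) {
  cat(sprintf("%s power: effect %.3g, n = %d, alpha = %.3g -> %.4f (%d%%)\n",
              x$test, x$effect_size, x$n, x$alpha, x$power, x$percent))
  invisible(x)
}
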