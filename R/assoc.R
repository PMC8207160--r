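# Association battery: Pearson correlations, group comparisons,
# likelihood-ratio tests against an intercept-only model, and Bonferroni
# control.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (delegated to [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors (`n >= 3`, finite, non-constant).
#' @return list: `r`, `p`, `n`.
#' @export
pearson_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3L, "need at least 3 paired finite values")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Group comparison: one-way ANOVA and Kruskal-Wallis
#'
#' Both tests are always computed; a Shapiro-Wilk normality check on the
#' pooled model residuals gates which one is `recommended` (ANOVA when
#' normality is not rejected at `shapiro_alpha`, Kruskal-Wallis otherwise,
#' matching common practice of switching to the rank test for clearly
#' non-normal data). Groups with fewer than 2 members are dropped with a
#' warning.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param shapiro_alpha significance level of the normality gate.
#' @return list: `anova_F`, `anova_p`, `kw_H`, `kw_p`, `shapiro_p`,
#'   `recommended` (`"anova"` or `"kruskal"`), `groups_used`.
#' @export
group_tests <- function(values, groups, shapiro_alpha = 0.05) {
  groups <- as.character(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  assert_that(nlevels(g) >= 2L, "need at least 2 usable groups")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  kw <- stats::kruskal.test(values, g)
  res <- stats::residuals(fit)
  sh_p <- if (length(res) >= 3 && length(res) <= 5000 &&
              stats::sd(res) > 0) stats::shapiro.test(res)$p.value
          else NA_real_
  list(anova_F = an$`F value`[1], anova_p = an$`Pr(>F)`[1],
       kw_H = unname(kw$statistic), kw_p = kw$p.value,
       shapiro_p = sh_p,
       recommended = if (is.na(sh_p) || sh_p >= shapiro_alpha) "anova"
                     else "kruskal",
       groups_used = levels(g))
}

#' Likelihood-ratio test of a bivariate linear model against the null
#'
#' Fits `y ~ 1` and `y ~ x` by least squares and compares them with the
#' maximum-likelihood normal-theory statistic
#' `chi2 = n * log(RSS0 / RSS1)`, referred to a chi-squared distribution
#' whose df is the number of added parameters (1 for a numeric predictor;
#' for a single numeric x this equals `-n * log(1 - r^2)`). Factors are
#' admitted via their dummy expansion.
#'
#' @param y numeric response (treated as normal).
#' @param x predictor (numeric or factor, non-constant).
#' @return list: `chi2`, `p`, `df`, `n`.
#' @export
lrt_vs_null <- function(y, x) {
  ok <- is.finite(y) & !is.na(x)
  if (is.numeric(x)) ok <- ok & is.finite(x)
  y <- y[ok]
  x <- if (is.numeric(x)) x[ok] else factor(as.character(x)[ok])
  n <- length(y)
  assert_that(n >= 3L, "need at least 3 observations")
  if (is.numeric(x)) assert_that(stats::sd(x) > 0, "constant predictor")
  else assert_that(nlevels(x) >= 2L, "constant predictor")
  fit0 <- stats::lm(y ~ 1)
  fit1 <- stats::lm(y ~ x)
  rss0 <- sum(stats::residuals(fit0)^2)
  rss1 <- sum(stats::residuals(fit1)^2)
  df <- fit1$rank - fit0$rank
  chi2 <- if (rss1 <= 0) Inf else n * log(rss0 / rss1)
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df, n = n)
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha_family family-wise error rate (default .05).
#' @param m_tests number of tests in the family.
#' @return `alpha_family / m_tests`.
#' @export
#' @examples
#' bonferroni(0.05, 5)   # 0.01
#' bonferroni(0.05, 4)   # 0.0125
bonferroni <- function(alpha_family = 0.05, m_tests) {
  assert_that(is_count(m_tests), "m_tests must be a positive integer")
  alpha_family / m_tests
}

#' Run the FA association battery
#'
#' Likelihood-ratio tests of each factor against the intercept-only model,
#' for one or more responses, at a Bonferroni-corrected per-test alpha.
#'
#' @param data data frame holding responses and factors.
#' @param responses names of response columns (e.g. shape/size FA).
#' @param factors names of predictor columns.
#' @param level label recorded in the output (`"individual"` or
#'   `"population"`).
#' @param alpha_family family-wise error rate.
#' @param m_tests Bonferroni divisor; defaults to the number of factors.
#' @return data frame: `level`, `response`, `factor`, `chi2`, `p`,
#'   `alpha_used`, `significant`.
#' @export
association_battery <- function(data, responses, factors, level,
                                alpha_family = 0.05,
                                m_tests = length(factors)) {
  alpha <- bonferroni(alpha_family, m_tests)
  rows <- list()
  for (resp in responses) {
    for (fac in factors) {
      res <- try(lrt_vs_null(data[[resp]], data[[fac]]), silent = TRUE)
      chi2 <- if (inherits(res, "try-error")) NA_real_ else res$chi2
      p <- if (inherits(res, "try-error")) NA_real_ else res$p
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, response = resp, factor = fac,
        chi2 = chi2, p = p, alpha_used = alpha,
        significant = is.finite(p) && p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
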