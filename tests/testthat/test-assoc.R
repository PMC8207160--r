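test_that("Pearson correlation: closed form, symmetry, affine invariance", {
  # 4-point toy checked against the covariance/SD closed form by hand
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  r_hand <- sum((x - 2.5) * (y - 2.5)) /
    sqrt(sum((x - 2.5)^2) * sum((y - 2.5)^2))
  res <- pearson_assoc(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$r, pearson_assoc(y, x)$r)
  expect_equal(pearson_assoc(10 * x - 3, y / 7 + 2)$r, res$r,
               tolerance = 1e-12)
  # perfect linearity
  res2 <- pearson_assoc(x, 2 * x + 1)
  expect_equal(res2$r, 1)
  expect_lt(res2$p, 1e-10)
  expect_error(pearson_assoc(c(1, 1, 1), y[1:3]), "variance")
})

test_that("group tests match hand-computed F and H", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  res <- group_tests(v, g)
  expect_equal(res$anova_F, 13.5, tolerance = 1e-12)
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(res$kw_H, 12 / 42 * (12 + 75) - 21, tolerance = 1e-12)
  # identical values: H = 0 (tie-corrected H is NaN -> kruskal p 1)
  res2 <- group_tests(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_true(is.na(res2$kw_H) || res2$kw_H == 0)
  # undersized groups are dropped with a warning
  expect_warning(
    res3 <- group_tests(c(1, 2, 3, 4, 9), c(rep("a", 2), rep("b", 2), "c")),
    "dropping")
  expect_equal(res3$groups_used, c("a", "b"))
})

test_that("group-test p-values are calibrated under label shuffles", {
  set.seed(77)
  v <- rnorm(24)
  g <- rep(letters[1:3], each = 8)
  ps <- replicate(400, group_tests(v, sample(g))$anova_p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("LRT against the null: closed form and degenerate cases", {
  # chi2 = -n log(1 - r^2) for a numeric predictor
  set.seed(11)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  res <- lrt_vs_null(y, x)
  r <- cor(x, y)
  expect_equal(res$chi2, -20 * log(1 - r^2), tolerance = 1e-9)
  expect_equal(res$df, 1)
  # exactly uncorrelated data: chi2 = 0, p = 1
  x0 <- c(-1, 0, 1, 0)
  y0 <- c(0, 1, 0, 1)     # cor(x0, y0) = 0
  res0 <- lrt_vs_null(y0, x0)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  expect_error(lrt_vs_null(y, rep(2, 20)), "constant")
  # factor predictors use their dummy expansion
  resf <- lrt_vs_null(y, rep(c("u", "v"), 10))
  expect_equal(resf$df, 1)
})

test_that("LRT monotonicity in |r| at fixed n", {
  n <- 10
  x <- seq_len(n)
  chis <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    # construct y with exactly correlation rho to x
    e <- stats::residuals(lm(rnorm(n) ~ x))
    e <- e / sd(e)
    xs <- (x - mean(x)) / sd(x)
    lrt_vs_null(rho * xs + sqrt(1 - rho^2) * e, x)$chi2
  }, numeric(1))
  expect_true(all(diff(chis) > 0))
  expect_true(all(chis >= 0))
})

test_that("small-sample LRT type-I error is near (somewhat above) nominal", {
  set.seed(123)
  rej <- mean(replicate(1000, {
    lrt_vs_null(rnorm(8), rnorm(8))$p < 0.0125
  }))
  # the n log(RSS0/RSS1) statistic is liberal at n = 8; the measured rate
  # stays in a band around nominal rather than at it
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.05)
})

test_that("Bonferroni alphas reproduce the two family sizes", {
  expect_equal(bonferroni(0.05, 5), 0.01)
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), "positive integer")
})

test_that("association battery assembles LRT rows with shared alpha", {
  set.seed(21)
  df <- data.frame(shape_fa = rnorm(30), habitat = runif(30),
                   sex = rep(c("F", "M"), 15), ho = runif(30))
  tab <- association_battery(df, "shape_fa", c("habitat", "sex", "ho"),
                             level = "individual", m_tests = 5)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$alpha_used == 0.01))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  expect_equal(tab$significant, tab$p < tab$alpha_used)
})
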