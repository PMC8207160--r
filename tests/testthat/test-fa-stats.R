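test_that("sequential SS matches the balanced cell-mean oracle exactly", {
  d <- toy_balanced_dataset(n_ind = 3, n_img = 2, n_dig = 2, k = 4,
                            seed = 11)
  g <- gpa_align(reflect_side(d, "right"))

  # shape
  a <- procrustes_anova(g)
  Y <- t(apply(g$aligned, 3, as.vector))
  o <- anova_ss_oracle(Y, g$info)
  expect_equal(a$SS[a$effect == "individual"], o$individual,
               tolerance = 1e-9)
  expect_equal(a$SS[a$effect == "side"], o$side, tolerance = 1e-9)
  expect_equal(a$SS[a$effect == "individual:side"], o$interaction,
               tolerance = 1e-9)
  expect_equal(a$SS[a$effect == "error1"], o$error1, tolerance = 1e-9)
  expect_equal(a$SS[a$effect == "residual"], o$residual, tolerance = 1e-9)
  # decomposition is exact: components add to the total SS
  tot <- sum(sweep(Y, 2, colMeans(Y))^2)
  expect_equal(sum(a$SS), tot, tolerance = 1e-9)

  # size
  s <- size_anova(g)
  os <- anova_ss_oracle(matrix(g$centroid_sizes, ncol = 1), g$info)
  expect_equal(s$SS, unlist(os, use.names = FALSE), tolerance = 1e-9)
})

test_that("structural df follow the design (shape x (2k-4), size x 1)", {
  d <- toy_balanced_dataset(n_ind = 5, n_img = 2, n_dig = 3, k = 10,
                            seed = 12)
  g <- gpa_align(reflect_side(d, "right"))
  a <- procrustes_anova(g)
  expect_equal(a$df, c(4 * 16, 16, 4 * 16, 5 * 2 * (2 - 1) * 16,
                       5 * 2 * 2 * (3 - 1) * 16))
  s <- size_anova(g)
  expect_equal(s$df, c(4, 1, 4, 10, 40))
})

test_that("all-identical configurations give zero SS everywhere", {
  base <- default_mean_shape(5)
  cfgs <- rep(list(base), 8)
  info <- expand.grid(specimen = c("a", "b"), side = c("left", "right"),
                      image_rep = 1L, digit_rep = 1:2,
                      stringsAsFactors = FALSE)
  d <- landmark_dataset(cfgs, info)
  g <- gpa_align(d)
  s <- size_anova(g)
  expect_true(all(s$SS < 1e-18))
})

test_that("FA detection applies both the p and the F-ratio criteria", {
  tab <- data.frame(
    effect = c("individual", "side", "individual:side", "error1",
               "residual"),
    SS = 1, df = 1, MS = 1,
    F = c(2, 1, 8.89, 0.63, NA),
    p = c(.01, .5, 1e-5, 1, NA),
    denominator = NA, stringsAsFactors = FALSE)
  res <- detect_fa(tab)
  expect_true(res$detected)          # 8.89 > 10 * 0.63
  tab$F[3] <- 5; tab$F[4] <- 1
  expect_false(detect_fa(tab)$detected)   # ratio 5 < 10
  expect_true(detect_fa(tab)$significant)
  tab$F[3] <- 50; tab$p[3] <- 0.2
  expect_false(detect_fa(tab)$detected)   # not significant
  expect_error(detect_fa(tab[1:2, ]), "lacks")
})

test_that("interaction MS recovers the injected FA variance", {
  sigma_fa <- 0.01
  m <- landmark_model(n_individuals = 200, sigma_ind = 0.02,
                      da_vector = 0.003, sigma_fa = sigma_fa,
                      sigma_image = 5e-4, sigma_digit = 2e-3,
                      n_images = 2, n_digitizings = 3,
                      sigma_size = 0, seed = 17)
  d <- gen_landmark_dataset(m)
  g <- gpa_align(reflect_side(d, "right"))
  a <- procrustes_anova(g)
  ms_int <- a$MS[a$effect == "individual:side"]
  ms_err <- a$MS[a$effect == "error1"]
  # the +/- a_i/2 side effects contribute SS_int = r * sum_i (a_i - a_bar)^2 / 2
  # over r = m * d replicates, so E[MS_int] = E[MS_err1] + (m*d/2) sigma_fa^2
  est <- 2 * (ms_int - ms_err) / (2 * 3)
  expect_lt(abs(est - sigma_fa^2) / sigma_fa^2, 0.25)
})

test_that("Mahalanobis scores: definition cases and diagonal oracle", {
  # variation confined to two coordinates -> standardized Euclidean
  k <- 5
  base <- default_mean_shape(k)
  n <- 9
  set.seed(33)
  dev_x <- rnorm(n, 0, 0.03)   # landmark 2, x
  dev_y <- rnorm(n, 0, 0.01)   # landmark 4, y
  aligned <- array(NA_real_, c(k, 2, 2 * n))
  info <- data.frame(specimen = rep(paste0("s", 1:n), each = 2),
                     side = rep(c("left", "right"), n),
                     image_rep = 1L, digit_rep = 1L,
                     stringsAsFactors = FALSE)
  for (i in 1:n) {
    L <- base
    L[2, 1] <- L[2, 1] + dev_x[i]
    L[4, 2] <- L[4, 2] + dev_y[i]
    aligned[, , 2 * i - 1] <- L
    aligned[, , 2 * i] <- base
  }
  pr <- fake_procrustes(aligned, info)
  sc <- mahalanobis_shape_fa(pr)
  A <- cbind(dev_x, dev_y)
  expected <- sqrt(stats::mahalanobis(A, colMeans(A), stats::cov(A)))
  expect_equal(sc$shape_fa, unname(expected), tolerance = 1e-8)

  # a specimen whose asymmetry equals the mean asymmetry scores ~0
  shift <- colMeans(A)
  L <- base
  L[2, 1] <- L[2, 1] + shift[1]
  L[4, 2] <- L[4, 2] + shift[2]
  aligned2 <- array(c(aligned, L, base), c(k, 2, 2 * n + 2))
  info2 <- rbind(info, data.frame(
    specimen = "mean_spec", side = c("left", "right"),
    image_rep = 1L, digit_rep = 1L))
  sc2 <- mahalanobis_shape_fa(fake_procrustes(aligned2, info2))
  expect_lt(sc2$shape_fa[sc2$specimen == "mean_spec"], 1e-6)

  # two-specimen datasets give two equal scores
  sc3 <- mahalanobis_shape_fa(fake_procrustes(
    aligned[, , 1:4], info[1:4, ]))
  expect_equal(sc3$shape_fa[1], sc3$shape_fa[2], tolerance = 1e-10)
})

test_that("Mahalanobis scores are invariant to global rotation", {
  d <- toy_balanced_dataset(n_ind = 20, n_img = 1, n_dig = 1, k = 6,
                            seed = 41, sigma = 0.02)
  g1 <- gpa_align(reflect_side(d, "right"))
  th <- 1.1
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  g2 <- g1
  for (i in seq_len(dim(g1$aligned)[3])) {
    g2$aligned[, , i] <- g1$aligned[, , i] %*% R
  }
  expect_equal(mahalanobis_shape_fa(g1)$shape_fa,
               mahalanobis_shape_fa(g2)$shape_fa, tolerance = 1e-8)
})

test_that("size FA index is the replicate-mean side difference", {
  # CS left replicates (10.0, 10.2), right (9.8, 10.0) -> +0.2
  base <- default_mean_shape(4)
  mk <- function(cs) base * cs
  cfgs <- list(mk(10.0), mk(10.2), mk(9.8), mk(10.0))
  info <- data.frame(specimen = "s1",
                     side = c("left", "left", "right", "right"),
                     image_rep = c(1L, 2L, 1L, 2L), digit_rep = 1L,
                     stringsAsFactors = FALSE)
  g <- gpa_align(landmark_dataset(cfgs, info))
  idx <- size_fa_index(g)
  expect_equal(idx$size_fa_signed, 0.2, tolerance = 1e-9)
  expect_equal(idx$size_fa_abs, 0.2, tolerance = 1e-9)

  # perfectly symmetric specimen scores zero
  cfgs2 <- list(mk(10), mk(10))
  info2 <- info[c(1, 3), ]
  g2 <- gpa_align(landmark_dataset(cfgs2, info2))
  expect_equal(size_fa_index(g2)$size_fa_signed, 0)
})

test_that("mean absolute size FA follows the folded normal", {
  sigma_fa <- 0.02
  m <- landmark_model(n_individuals = 300, sigma_ind = 0, da_vector = 0,
                      sigma_fa = sigma_fa, sigma_image = 0,
                      sigma_digit = 0, sigma_size = 0,
                      n_images = 1, n_digitizings = 1, scale = 1,
                      seed = 53)
  d <- gen_landmark_dataset(m)
  g <- gpa_align(reflect_side(d, "right"))
  idx <- size_fa_index(g)
  # CS(left) - CS(right) ~ N(0, sigma_fa^2) to first order, so
  # E|diff| = sigma_fa * sqrt(2 / pi)
  expected <- sigma_fa * sqrt(2 / pi)
  expect_lt(abs(mean(idx$size_fa_abs) - expected) / expected, 0.12)
})
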