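test_that("degenerate noise model reproduces the mean shape exactly", {
  m <- landmark_model(n_individuals = 3, sigma_ind = 0, da_vector = 0,
                      sigma_fa = 0, sigma_image = 0, sigma_digit = 0,
                      sigma_size = 0, seed = 1)
  d <- gen_landmark_dataset(m)
  mirror <- m$mean_shape
  mirror[, 1] <- -mirror[, 1]
  for (i in seq_len(dim(d$coords)[3])) {
    expected <- if (d$info$side[i] == "left") m$mean_shape else mirror
    expect_equal(d$coords[, , i], expected, tolerance = 1e-12)
  }
})

test_that("signed left-right asymmetry has variance sigma_fa^2", {
  m <- landmark_model(n_individuals = 200, sigma_ind = 0, da_vector = 0,
                      sigma_fa = 0.02, sigma_image = 0, sigma_digit = 0,
                      sigma_size = 0, n_images = 1, n_digitizings = 1,
                      seed = 5)
  d <- gen_landmark_dataset(m)
  left <- d$coords[, , d$info$side == "left"]
  right <- d$coords[, , d$info$side == "right"]
  right[, 1, ] <- -right[, 1, ]          # un-mirror
  asym <- left - right
  v <- mean(apply(asym, c(1, 2), var))   # avg per-coordinate variance
  expect_lt(abs(v - 4e-4) / 4e-4, 0.20)
})

test_that("seed contract: same seed identical, different seeds differ", {
  m1 <- landmark_model(n_individuals = 4, seed = 1)
  m2 <- landmark_model(n_individuals = 4, seed = 2)
  d1a <- gen_landmark_dataset(m1)
  d1b <- gen_landmark_dataset(m1)
  d2 <- gen_landmark_dataset(m2)
  expect_identical(d1a$coords, d1b$coords)
  expect_false(identical(d1a$coords, d2$coords))
})

test_that("model validation rejects bad parameters", {
  expect_error(landmark_model(sigma_fa = -1), "SD")
  expect_error(landmark_model(n_images = 0), "n_images")
  expect_error(landmark_model(
    mean_shape = cbind(1:4, 2 * (1:4))), "collinear")
  expect_error(genotype_model(list(c(0.5, 0.6))), "sum to 1")
  expect_error(genotype_model(list(c(0.5, 0.5)), inbreeding_f = 1),
               "inbreeding_f")
  expect_error(gen_habitat_raster(1.2), "proportion")
})

test_that("genotypes under F = 0 hit Hardy-Weinberg heterozygosity", {
  gm <- genotype_model(list(c(0.5, 0.5)), inbreeding_f = 0,
                       n_individuals = 10000, seed = 3)
  gt <- gen_genotypes(gm)
  ho <- observed_heterozygosity(gt)$population$ho
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(ho - 0.5), 3 * se)
})

test_that("strong inbreeding gives nearly all homozygotes", {
  gm <- genotype_model(list(c(0.5, 0.5)), inbreeding_f = 0.999,
                       n_individuals = 500, seed = 4)
  gt <- gen_genotypes(gm)
  expect_lt(observed_heterozygosity(gt)$population$ho, 0.02)
})

test_that("expected Ho is (1 - F)(1 - sum p^2) across loci", {
  freqs <- replicate(7, rep(0.2, 5), simplify = FALSE)
  gm <- genotype_model(freqs, inbreeding_f = 0.12, n_individuals = 500,
                       seed = 6)
  gt <- gen_genotypes(gm)
  ho <- mean(observed_heterozygosity(gt)$individual$ho)
  expected <- (1 - 0.12) * 0.8
  se <- sqrt(expected * (1 - expected) / (500 * 7))
  expect_lt(abs(ho - expected), 4 * se)
})

test_that("habitat raster hits the requested proportion", {
  expect_equal(mean(gen_habitat_raster(1, c(20, 20), seed = 1)$grid), 1)
  expect_equal(mean(gen_habitat_raster(0, c(20, 20), seed = 1)$grid), 0)
  r <- gen_habitat_raster(0.3, c(200, 200), smoothing = 3, seed = 2)
  expect_true(mean(r$grid) >= 0.29 && mean(r$grid) <= 0.31)
  # reproducibility
  r2 <- gen_habitat_raster(0.3, c(200, 200), smoothing = 3, seed = 2)
  expect_identical(r$grid, r2$grid)
})

test_that("study bundle has coherent bookkeeping", {
  scn <- study_scenario(habitat_props = 0.5, n_per_site = 11)
  b <- gen_study(scn, seed = 9)
  expect_equal(nrow(b$sites), 1)
  expect_equal(length(unique(b$landmarks$info$specimen)), 11)
  expect_equal(dim(b$landmarks$coords)[3], 11 * 2 * 2 * 3)
  expect_equal(length(b$genotypes$ids), 11)
  expect_equal(nrow(b$covariates), 11)
  # seed determinism across the whole bundle
  b2 <- gen_study(scn, seed = 9)
  expect_identical(b$landmarks$coords, b2$landmarks$coords)
  expect_identical(b$genotypes$alleles, b2$genotypes$alleles)
  expect_identical(b$rasters[[1]]$grid, b2$rasters[[1]]$grid)
})
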