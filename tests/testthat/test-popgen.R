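toy_gt <- function(pairs, population = "p1", loci = NULL) {
  # pairs: list of n x 2 matrices, one per locus
  n <- nrow(pairs[[1]])
  arr <- array(0L, c(n, length(pairs), 2))
  for (j in seq_along(pairs)) arr[, j, ] <- as.matrix(pairs[[j]])
  if (!is.null(loci)) dimnames(arr) <- list(NULL, loci, c("a", "b"))
  genotype_table(sprintf("i%02d", seq_len(n)), rep(population, n), arr)
}

test_that("observed heterozygosity: arithmetic, bounds, and exclusions", {
  # individual het at 4 of 7 loci -> 4/7
  pairs <- lapply(1:7, function(j) {
    if (j <= 4) cbind(1L, 2L) else cbind(1L, 1L)
  })
  gt <- toy_gt(lapply(pairs, function(p) p[rep(1, 3), , drop = FALSE]))
  ho <- observed_heterozygosity(gt)
  expect_equal(ho$individual$ho, rep(4 / 7, 3))
  expect_equal(ho$population$ho, 4 / 7)

  # all homozygous -> 0; missing loci do not distort the denominator
  gt2 <- toy_gt(list(cbind(c(1L, 1L, 0L), c(1L, 1L, 0L)),
                     cbind(c(2L, 2L, 2L), c(2L, 2L, 2L))))
  ho2 <- observed_heterozygosity(gt2)
  expect_equal(ho2$population$ho, 0)
  expect_equal(ho2$individual$n_typed, c(2L, 2L, 1L))

  # an individual missing everywhere is excluded and reported
  gt3 <- toy_gt(list(cbind(c(1L, 0L), c(2L, 0L))))
  ho3 <- observed_heterozygosity(gt3)
  expect_equal(ho3$excluded, "i02")
  expect_equal(nrow(ho3$individual), 1)
  expect_true(all(ho3$individual$ho >= 0 & ho3$individual$ho <= 1))
})

test_that("Weir-Cockerham f hits the closed-form boundary cases", {
  # all homozygotes, two alleles at 0.5 -> f = 1
  gt <- toy_gt(list(cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))))
  expect_equal(fis_weir_cockerham(gt)$multilocus$fis, 1)
  # all heterozygotes -> f = -1
  gt2 <- toy_gt(list(cbind(rep(1L, 6), rep(2L, 6))))
  expect_equal(fis_weir_cockerham(gt2)$multilocus$fis, -1)
  # monomorphic locus skipped and reported as NA
  gt3 <- toy_gt(list(cbind(rep(1L, 4), rep(1L, 4)),
                     cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))))
  res <- fis_weir_cockerham(gt3)
  expect_true(is.na(res$by_locus$f[res$by_locus$locus == "locus_1"]))
  expect_equal(res$multilocus$n_loci_used, 1L)
})

test_that("Weir-Cockerham f estimates the simulation F consistently", {
  freqs <- replicate(7, rep(0.2, 5), simplify = FALSE)
  f_hat <- vapply(1:20, function(s) {
    gt <- gen_genotypes(genotype_model(freqs, 0.12, 500, seed = 600 + s))
    fis_weir_cockerham(gt)$multilocus$fis
  }, numeric(1))
  expect_gte(mean(f_hat >= 0.08 & f_hat <= 0.16), 0.9)
  # bias shrinks with n
  bias_at <- function(n, s) {
    gt <- gen_genotypes(genotype_model(freqs, 0.12, n, seed = s))
    abs(fis_weir_cockerham(gt)$multilocus$fis - 0.12)
  }
  b_small <- mean(vapply(1:8, function(s) bias_at(100, 700 + s),
                         numeric(1)))
  b_large <- mean(vapply(1:8, function(s) bias_at(2000, 800 + s),
                         numeric(1)))
  expect_lt(b_large, b_small)
})

test_that("HWE enumeration matches the independent biallelic oracle", {
  cases <- list(c(25, 50, 25), c(10, 2, 10), c(0, 20, 0), c(7, 11, 3))
  for (cs in cases) {
    gt <- toy_gt(list(cbind(
      c(rep(1L, cs[1]), rep(1L, cs[2]), rep(2L, cs[3])),
      c(rep(1L, cs[1]), rep(2L, cs[2]), rep(2L, cs[3])))))
    res <- hwe_exact(gt, 1, method = "enumeration")
    expect_equal(res$p, hwe_biallelic_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-9)
  }
  # perfect HWE proportions are the most probable table: p -> 1
  gt_hwe <- toy_gt(list(cbind(
    c(rep(1L, 25), rep(1L, 50), rep(2L, 25)),
    c(rep(1L, 25), rep(2L, 50), rep(2L, 25)))))
  expect_gt(hwe_exact(gt_hwe, 1, method = "enumeration")$p, 0.5)
  # 20 heterozygotes and nothing else: strong excess
  expect_lte(hwe_exact(toy_gt(list(cbind(rep(1L, 20), rep(2L, 20)))),
                       1, method = "enumeration")$p, 0.01)
  # monomorphic flagged with p = 1
  res_m <- hwe_exact(toy_gt(list(cbind(rep(1L, 10), rep(1L, 10)))), 1)
  expect_true(res_m$monomorphic)
  expect_equal(res_m$p, 1)
})

test_that("Monte-Carlo HWE agrees with enumeration on a 3-allele table", {
  set.seed(5)
  a1 <- sample(1:3, 40, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  a2 <- sample(1:3, 40, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  gt <- toy_gt(list(cbind(pmin(a1, a2), pmax(a1, a2))))
  p_en <- hwe_exact(gt, 1, method = "enumeration")$p
  res_mc <- hwe_exact(gt, 1, method = "mc", reps = 1e5, seed = 9)
  expect_lt(abs(res_mc$p - p_en), 3 * res_mc$se)
})

test_that("LD permutation: perfect association, determinism, errors", {
  set.seed(7)
  a <- replicate(2, sample(1:4, 50, replace = TRUE))
  gt <- toy_gt(list(cbind(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2])),
                    cbind(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))))
  res <- ld_permutation(gt, 1, 2, n_perm = 999, seed = 3)
  expect_lt(res$p, 0.01)   # duplicated locus: near-minimal p
  res2 <- ld_permutation(gt, 1, 2, n_perm = 999, seed = 3)
  expect_identical(res$p, res2$p)
  gt_small <- toy_gt(list(cbind(1:3, 1:3), cbind(1:3, 1:3)))
  expect_error(ld_permutation(gt_small, 1, 2), "at least 5")
})

test_that("LD p-values are uniform (dense tables) and never
          anticonservative (sparse tables) for independent loci", {
  # biallelic loci: genotype tables are dense, few permutation ties, and
  # the p distribution is close to uniform
  ps <- vapply(1:150, function(s) {
    gt <- gen_genotypes(genotype_model(
      replicate(2, c(0.5, 0.5), simplify = FALSE), 0, 60,
      seed = 900 + s))
    ld_permutation(gt, 1, 2, n_perm = 199, seed = s)$p
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.07)
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
  expect_lte(mean(ps <= 0.25), 0.25 + 3 * sqrt(0.25 * 0.75 / 150))
  # multi-allelic loci give sparse 10x10 genotype tables: the discrete
  # permutation p is conservative (stochastically above uniform) but must
  # never reject more often than nominal
  ps4 <- vapply(1:60, function(s) {
    gt <- gen_genotypes(genotype_model(
      replicate(2, rep(0.25, 4), simplify = FALSE), 0, 60,
      seed = 4900 + s))
    ld_permutation(gt, 1, 2, n_perm = 199, seed = s)$p
  }, numeric(1))
  expect_gte(mean(ps4), 0.45)
  expect_lte(mean(ps4 <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("genotype CSV round-trips", {
  gt <- gen_genotypes(genotype_model(
    replicate(3, c(0.4, 0.6), simplify = FALSE), 0.1, 12, seed = 2),
    population = "popA")
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gt, f)
  gt2 <- read_genotypes(f)
  expect_identical(gt$alleles, gt2$alleles)
  expect_identical(gt$populations, gt2$populations)
})
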