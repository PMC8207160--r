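# Genotypic linkage-disequilibrium permutation test.

# G-like log-likelihood-ratio statistic of a two-way contingency table
.g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / E[nz]))
}

# unordered genotype labels for one locus
.geno_labels <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Association between the genotypes at two loci, tested within one
#' population. The statistic is the G (log-likelihood-ratio) value of the
#' genotype x genotype contingency table; the null distribution is built by
#' permuting one locus's genotypes across individuals, which breaks any
#' between-locus association while preserving both single-locus genotype
#' distributions. The p-value uses the add-one permutation correction
#' `p = (1 + #{G* >= G_obs}) / (n_perm + 1)`.
#'
#' @param gt a [genotype_table()].
#' @param locus_a,locus_b locus names or indices.
#' @param population population label (default: all individuals).
#' @param n_perm number of permutations.
#' @param seed optional RNG seed (same seed, same p-value).
#' @return list: `p`, `g_obs`, `n` (individuals typed at both loci).
#' @export
ld_permutation <- function(gt, locus_a, locus_b, population = NULL,
                           n_perm = 10000, seed = NULL) {
  sel <- if (is.null(population)) rep(TRUE, length(gt$ids))
         else gt$populations == population
  ja <- if (is.character(locus_a)) match(locus_a, gt$loci) else locus_a
  jb <- if (is.character(locus_b)) match(locus_b, gt$loci) else locus_b
  a1 <- gt$alleles[sel, ja, 1]; a2 <- gt$alleles[sel, ja, 2]
  b1 <- gt$alleles[sel, jb, 1]; b2 <- gt$alleles[sel, jb, 2]
  typed <- a1 > 0L & b1 > 0L
  assert_that(sum(typed) >= 5L,
              "need at least 5 individuals typed at both loci")
  ga <- factor(.geno_labels(a1[typed], a2[typed]))
  gb <- factor(.geno_labels(b1[typed], b2[typed]))
  g_obs <- .g_statistic(table(ga, gb))
  hits <- with_seed(seed, {
    h <- 0L
    for (r in seq_len(n_perm)) {
      if (.g_statistic(table(ga, sample(gb))) >= g_obs - 1e-12) h <- h + 1L
    }
    h
  })
  list(p = (1 + hits) / (n_perm + 1), g_obs = g_obs, n = sum(typed))
}

#' Pairwise LD p-value matrix
#'
#' Runs [ld_permutation()] for every locus pair within a population.
#'
#' @inheritParams ld_permutation
#' @return symmetric matrix of permutation p-values (diagonal `NA`).
#' @export
ld_all_pairs <- function(gt, population = NULL, n_perm = 10000,
                         seed = NULL) {
  L <- length(gt$loci)
  P <- matrix(NA_real_, L, L, dimnames = list(gt$loci, gt$loci))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      res <- try(ld_permutation(gt, i, j, population, n_perm,
                                seed = derive_seed(seed, i * L + j)),
                 silent = TRUE)
      if (!inherits(res, "try-error")) P[i, j] <- P[j, i] <- res$p
    }
  }
  P
}
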