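# Exact Hardy-Weinberg tests.
#
# Conditional on the observed allele counts, the probability of a genotype
# array {f_ab} (a <= b) under random union of gametes is Levene's
# distribution:
#   P(f | n, counts) = n! * prod_a(n_a!) * 2^H / ((2n)! * prod_{a<=b} f_ab!)
# with H the number of heterozygotes. The exact p-value sums the
# probability of all arrays no more probable than the observed one
# (the classical exact-test ordering). Small problems are fully
# enumerated; larger ones fall back to Monte-Carlo shuffling of the
# allele vector (Guo & Thompson style).

# log P(f | allele counts) up to the array-independent constant
# log(n!) + sum log(n_a!) - log((2n)!); we keep the full value so
# enumeration probabilities sum to 1.
.hwe_logprob <- function(f, allele_counts) {
  n <- sum(f[upper.tri(f, diag = TRUE)])   # individuals, not allele slots
  H <- sum(f[upper.tri(f)])
  lgamma(n + 1) + sum(lgamma(allele_counts + 1)) + H * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(f[upper.tri(f, diag = TRUE)] + 1))
}

# Enumerate all symmetric genotype-count arrays with the given allele
# counts. Calls `visit(logp)` for each; aborts (returns FALSE) when more
# than `max_tables` arrays are generated.
.hwe_enumerate <- function(allele_counts, visit, max_tables = 1e6) {
  A <- length(allele_counts)
  f <- matrix(0L, A, A)
  count <- 0L
  ok <- TRUE
  rec <- function(a, b, remaining) {
    # fill genotype (a,b); remaining = allele counts still to place
    if (!ok) return()
    if (a > A) {
      if (all(remaining == 0L)) {
        count <<- count + 1L
        if (count > max_tables) { ok <<- FALSE; return() }
        visit(.hwe_logprob(f, allele_counts))
      }
      return()
    }
    nxt_a <- if (b == A) a + 1L else a
    nxt_b <- if (b == A) nxt_a else b + 1L
    if (a == b) {
      top <- remaining[a] %/% 2L
      for (x in 0:top) {
        f[a, a] <<- x
        rem <- remaining; rem[a] <- rem[a] - 2L * x
        rec(nxt_a, nxt_b, rem)
      }
      f[a, a] <<- 0L
    } else {
      top <- min(remaining[a], remaining[b])
      for (x in 0:top) {
        f[a, b] <<- x; f[b, a] <<- x
        rem <- remaining; rem[a] <- rem[a] - x; rem[b] <- rem[b] - x
        rec(nxt_a, nxt_b, rem)
      }
      f[a, b] <<- 0L; f[b, a] <<- 0L
    }
  }
  rec(1L, 1L, as.integer(allele_counts))
  ok
}

# genotype count matrix from two allele vectors (typed individuals only)
.genotype_counts <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  f <- matrix(0L, A, A, dimnames = list(alleles, alleles))
  i <- match(pmin(a1, a2), alleles)
  j <- match(pmax(a1, a2), alleles)
  for (g in seq_along(i)) f[i[g], j[g]] <- f[i[g], j[g]] + 1L
  f[lower.tri(f)] <- t(f)[lower.tri(f)]
  f
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for one locus in one population. With few enough
#' genotype arrays the null distribution is fully enumerated (Levene's
#' conditional probabilities); otherwise a Monte-Carlo version shuffles the
#' allele vector `reps` times. The p-value is the total probability of
#' arrays no more probable than the observed one.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @param population population label (default: all individuals).
#' @param method `"auto"` (enumerate when feasible), `"enumeration"` or
#'   `"mc"`.
#' @param reps Monte-Carlo shuffles.
#' @param seed optional RNG seed for the Monte-Carlo path.
#' @param max_tables enumeration budget before falling back to Monte-Carlo.
#' @return list: `p`, `method` used, `monomorphic` flag, and `se`
#'   (binomial standard error, Monte-Carlo only).
#' @export
hwe_exact <- function(gt, locus, population = NULL,
                      method = c("auto", "enumeration", "mc"),
                      reps = 1000, seed = NULL, max_tables = 1e6) {
  method <- match.arg(method)
  sel <- if (is.null(population)) rep(TRUE, length(gt$ids))
         else gt$populations == population
  j <- if (is.character(locus)) match(locus, gt$loci) else locus
  a1 <- gt$alleles[sel, j, 1]; a2 <- gt$alleles[sel, j, 2]
  typed <- a1 > 0L
  a1 <- a1[typed]; a2 <- a2[typed]
  assert_that(length(a1) >= 2L, "need at least 2 typed individuals")
  if (length(unique(c(a1, a2))) < 2L) {
    return(list(p = 1, method = "none", monomorphic = TRUE, se = NA_real_))
  }
  f <- .genotype_counts(a1, a2)
  counts <- rowSums(f) + diag(f)          # allele counts
  logp_obs <- .hwe_logprob(f, counts)
  tol <- 1e-9 * abs(logp_obs)             # tie tolerance on the log scale

  if (method != "mc") {
    acc <- 0
    done <- .hwe_enumerate(counts, function(lp) {
      if (lp <= logp_obs + tol) acc <<- acc + exp(lp)
    }, max_tables = max_tables)
    if (done) {
      return(list(p = min(acc, 1), method = "enumeration",
                  monomorphic = FALSE, se = NA_real_))
    }
    assert_that(method != "enumeration",
                "enumeration budget exceeded; use method = 'mc'")
  }
  # Monte-Carlo: shuffle the 2n allele vector, pair consecutive entries.
  # Only the heterozygote count and the per-genotype factorials vary
  # between shuffles, so work on tabulated pair indices directly.
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  pool <- match(c(a1, a2), alleles)
  n_ind <- length(a1)
  const <- lgamma(n_ind + 1) + sum(lgamma(counts + 1)) -
    lgamma(2 * n_ind + 1)
  odd <- seq(1, 2 * n_ind, 2)
  hits <- with_seed(seed, {
    h <- 0L
    for (r in seq_len(reps)) {
      perm <- sample(pool)
      p1 <- perm[odd]; p2 <- perm[odd + 1L]
      lo <- pmin(p1, p2); hi <- pmax(p1, p2)
      cnt <- tabulate((lo - 1L) * A + hi, A * A)
      H <- n_ind - sum(cnt[(seq_len(A) - 1L) * A + seq_len(A)])
      lp <- const + H * log(2) - sum(lgamma(cnt[cnt > 0L] + 1))
      if (lp <= logp_obs + tol) h <- h + 1L
    }
    h
  })
  p <- (1 + hits) / (reps + 1)
  list(p = p, method = "mc", monomorphic = FALSE,
       se = sqrt(p * (1 - p) / reps))
}
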