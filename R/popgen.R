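# Microsatellite summaries: genotype container, observed heterozygosity,
# and Weir-Cockerham / Nei inbreeding estimators. Exact Hardy-Weinberg and
# linkage-disequilibrium tests live in hwe.R / ld.R.

#' Microsatellite genotype table
#'
#' Unordered diploid allele pairs (positive integers, e.g. fragment sizes)
#' for individuals x loci; `0` or `NA` marks a missing call (both alleles
#' of a locus are missing together).
#'
#' @param ids character vector of individual identifiers.
#' @param populations population label per individual.
#' @param alleles integer array `n x L x 2`; dimnames of the second margin
#'   name the loci (defaults to `locus_1 ...`).
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(ids, populations, alleles) {
  assert_that(is.array(alleles) && length(dim(alleles)) == 3L &&
                dim(alleles)[3] == 2L,
              "alleles must be an n x L x 2 array")
  n <- dim(alleles)[1]
  assert_that(length(ids) == n && length(populations) == n,
              "ids/populations must match the allele array")
  alleles[is.na(alleles)] <- 0L
  assert_that(all(alleles >= 0), "allele codes must be positive (0 = missing)")
  half <- xor(alleles[, , 1] == 0L, alleles[, , 2] == 0L)
  assert_that(!any(half), "half-missing genotypes are not allowed")
  loci <- dimnames(alleles)[[2]] %||%
    paste0("locus_", seq_len(dim(alleles)[2]))
  dimnames(alleles) <- list(ids, loci, c("a", "b"))
  structure(list(ids = as.character(ids),
                 populations = as.character(populations),
                 loci = loci, alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals, %d loci, %d population(s)\n",
              length(x$ids), length(x$loci),
              length(unique(x$populations))))
  invisible(x)
}

#' Read / write genotype CSV
#'
#' Layout: `individual_id`, `population`, then two columns per locus named
#' `<locus>_a` and `<locus>_b`; `0` codes a missing call.
#'
#' @param path CSV file path.
#' @return [genotype_table()] (for `read_genotypes`).
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  acols <- grep("_a$", names(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  arr <- array(0L, c(nrow(df), length(loci), 2L),
               dimnames = list(NULL, loci, c("a", "b")))
  for (j in seq_along(loci)) {
    arr[, j, 1] <- as.integer(df[[paste0(loci[j], "_a")]])
    arr[, j, 2] <- as.integer(df[[paste0(loci[j], "_b")]])
  }
  genotype_table(df$individual_id, df$population, arr)
}

#' @rdname read_genotypes
#' @param gt a [genotype_table()].
#' @export
write_genotypes <- function(gt, path) {
  df <- data.frame(individual_id = gt$ids, population = gt$populations,
                   stringsAsFactors = FALSE)
  for (j in seq_along(gt$loci)) {
    df[[paste0(gt$loci[j], "_a")]] <- gt$alleles[, j, 1]
    df[[paste0(gt$loci[j], "_b")]] <- gt$alleles[, j, 2]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Observed heterozygosity per individual and per population
#'
#' Individual Ho is the proportion of heterozygous genotypes among that
#' individual's typed loci. Population Ho is the mean over loci of the
#' heterozygote proportion among individuals typed at that locus.
#' Individuals with no typed locus are excluded and listed.
#'
#' @param gt a [genotype_table()].
#' @return list with data frames `individual` (`individual_id`,
#'   `population`, `n_typed`, `ho`) and `population` (`population`, `ho`),
#'   plus `excluded` (ids with all loci missing).
#' @export
observed_heterozygosity <- function(gt) {
  n_ind <- dim(gt$alleles)[1]
  a1 <- matrix(gt$alleles[, , 1], nrow = n_ind)
  a2 <- matrix(gt$alleles[, , 2], nrow = n_ind)
  typed <- a1 > 0L
  het <- typed & (a1 != a2)
  n_typed <- rowSums(typed)
  excluded <- gt$ids[n_typed == 0L]
  keep <- n_typed > 0L
  ind <- data.frame(individual_id = gt$ids[keep],
                    population = gt$populations[keep],
                    n_typed = n_typed[keep],
                    ho = rowSums(het)[keep] / n_typed[keep],
                    stringsAsFactors = FALSE)
  pops <- unique(gt$populations)
  pop_ho <- vapply(pops, function(p) {
    sel <- gt$populations == p
    per_locus <- colSums(het[sel, , drop = FALSE]) /
      colSums(typed[sel, , drop = FALSE])
    mean(per_locus, na.rm = TRUE)
  }, numeric(1))
  list(individual = ind,
       population = data.frame(population = pops, ho = pop_ho,
                               stringsAsFactors = FALSE, row.names = NULL),
       excluded = excluded)
}

# Weir & Cockerham (1984) within-population components for one
# population x locus: per allele, c = observed het freq / 2 and
# b = n/(n-1) * [p(1-p) - (2n-1)/(4n) * h]. f = 1 - sum(c)/sum(b + c).
.wc_components <- function(a1, a2) {
  typed <- a1 > 0L
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  if (n < 2L) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)     # monomorphic: f undefined
  cnt <- table(factor(c(a1, a2), levels = alleles))
  p <- as.vector(cnt) / (2 * n)
  # h_a: frequency of individuals heterozygous *for allele a*
  h <- vapply(alleles, function(a)
    mean(xor(a1 == a, a2 == a)), numeric(1))
  b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cc <- h / 2
  list(b = b, c = cc, n = n)
}

#' Weir-Cockerham inbreeding coefficient (f) per population
#'
#' The small-sample estimator of F_IS from Weir & Cockerham (1984),
#' computed within each population: per-locus `f` and a multilocus value
#' that pools the variance components (summed over alleles and loci) before
#' forming the ratio `f = 1 - sum(c) / sum(b + c)`. Monomorphic
#' population x locus combinations carry no information and are skipped.
#' Nei's `1 - Ho/He` is reported alongside for comparison.
#'
#' @param gt a [genotype_table()].
#' @return list with `by_locus` (population, locus, f) and `multilocus`
#'   (population, fis, fis_nei, n_loci_used).
#' @export
fis_weir_cockerham <- function(gt) {
  pops <- unique(gt$populations)
  rows <- list()
  multi <- list()
  for (p in pops) {
    sel <- gt$populations == p
    sb <- sc <- 0
    used <- 0L
    for (j in seq_along(gt$loci)) {
      comp <- .wc_components(gt$alleles[sel, j, 1], gt$alleles[sel, j, 2])
      if (is.null(comp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, locus = gt$loci[j], f = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      f_loc <- 1 - sum(comp$c) / sum(comp$b + comp$c)
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, locus = gt$loci[j], f = f_loc,
        stringsAsFactors = FALSE)
      sb <- sb + sum(comp$b); sc <- sc + sum(comp$c)
      used <- used + 1L
    }
    nei <- .nei_fis(gt, p)
    multi[[length(multi) + 1L]] <- data.frame(
      population = p, fis = 1 - sc / (sb + sc), fis_nei = nei,
      n_loci_used = used, stringsAsFactors = FALSE)
  }
  list(by_locus = do.call(rbind, rows), multilocus = do.call(rbind, multi))
}

# Nei-style multilocus 1 - mean(Ho)/mean(He) with unbiased He
.nei_fis <- function(gt, pop) {
  sel <- gt$populations == pop
  ho <- he <- numeric(0)
  for (j in seq_along(gt$loci)) {
    a1 <- gt$alleles[sel, j, 1]; a2 <- gt$alleles[sel, j, 2]
    typed <- a1 > 0L
    a1 <- a1[typed]; a2 <- a2[typed]
    n <- length(a1)
    if (n < 2L || length(unique(c(a1, a2))) < 2L) next
    p <- as.vector(table(c(a1, a2))) / (2 * n)
    ho <- c(ho, mean(a1 != a2))
    he <- c(he, (2 * n / (2 * n - 1)) * (1 - sum(p^2)))
  }
  if (!length(he)) return(NA_real_)
  1 - mean(ho) / mean(he)
}
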