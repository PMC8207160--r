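# Independent oracles used across the test files. These deliberately
# re-derive quantities from first principles (cell means, closed forms,
# exhaustive grids) rather than calling the package's own code paths.

# Balanced nested ANOVA decomposition via explicit cell/marginal means.
# Y: n x p matrix; info: specimen/side/image_rep columns. Balanced designs
# only. Returns the five sums of squares.
anova_ss_oracle <- function(Y, info) {
  Y <- as.matrix(Y)
  grand <- colMeans(Y)
  mean_by <- function(f) {
    M <- rowsum(Y, f) / as.vector(table(f))
    M[as.character(f), , drop = FALSE]
  }
  m_ind <- mean_by(info$specimen)
  m_side <- mean_by(info$side)
  cell <- paste(info$specimen, info$side)
  m_cell <- mean_by(cell)
  img <- paste(cell, info$image_rep)
  m_img <- mean_by(img)
  ctr <- function(M) sweep(M, 2, grand)
  list(
    individual = sum(ctr(m_ind)^2),
    side = sum(ctr(m_side)^2),
    interaction = sum(sweep(m_cell - m_ind - m_side, 2, grand, "+")^2),
    error1 = sum((m_img - m_cell)^2),
    residual = sum((Y - m_img)^2))
}

# Exact Levene/Haldane HWE p-value for a biallelic genotype table,
# enumerating over the heterozygote count.
hwe_biallelic_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  logp <- function(h) {
    faa <- (na - h) / 2
    fbb <- (nb - h) / 2
    if (h < 0 || faa < 0 || fbb < 0 || faa != floor(faa)) return(-Inf)
    lfactorial(n) + lfactorial(na) + lfactorial(nb) + h * log(2) -
      lfactorial(2 * n) - lfactorial(faa) - lfactorial(h) -
      lfactorial(fbb)
  }
  hs <- seq(na %% 2, min(na, nb), by = 2)
  lps <- vapply(hs, logp, numeric(1))
  obs <- logp(n_ab)
  sum(exp(lps[lps <= obs + 1e-9 * abs(obs)]))
}

# Wrap raw aligned coordinates + metadata as a procrustes_result-shaped
# list (for FA-score oracles that construct aligned data directly).
fake_procrustes <- function(aligned, info, centroid_sizes = NULL) {
  structure(list(
    aligned = aligned,
    consensus = apply(aligned, c(1, 2), mean),
    centroid_sizes = centroid_sizes %||%
      rep(1, dim(aligned)[3]),
    iterations = 0L, converged = TRUE, info = info,
    k = dim(aligned)[1],
    design = list(n_images = max(info$image_rep),
                  n_digitizings = max(info$digit_rep))),
    class = "procrustes_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small balanced synthetic dataset for ANOVA tests.
toy_balanced_dataset <- function(n_ind = 3, n_img = 2, n_dig = 2, k = 4,
                                 seed = 11, sigma = 0.05) {
  set.seed(seed)
  base <- fluctasym::default_mean_shape(k)
  cfgs <- list(); rows <- list()
  for (i in seq_len(n_ind)) for (s in c("left", "right"))
    for (im in seq_len(n_img)) for (dg in seq_len(n_dig)) {
      cfgs[[length(cfgs) + 1L]] <- base +
        matrix(rnorm(2 * k, 0, sigma), k, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = paste0("t", i), side = s, image_rep = im,
        digit_rep = dg, stringsAsFactors = FALSE)
    }
  fluctasym::landmark_dataset(cfgs, do.call(rbind, rows))
}

# Full-Procrustes pairwise distance by exhaustive rotation search
# (both configurations centered and scaled to unit centroid size first).
procrustes_dist_grid <- function(a, b, step = 1e-4) {
  norm1 <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm1(a); b <- norm1(b)
  th <- seq(0, 2 * pi, by = step)
  best <- Inf; best_th <- NA
  for (t in th) {
    R <- rbind(c(cos(t), sin(t)), c(-sin(t), cos(t)))
    d <- sum((a - b %*% R)^2)
    if (d < best) { best <- d; best_th <- t }
  }
  list(dist2 = best, theta = best_th)
}
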