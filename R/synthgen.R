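# Synthetic-data generators: landmark datasets with a known
# variance-component structure, genotype tables with a known inbreeding
# coefficient, and spatially autocorrelated binary habitat rasters.

#' Default mandible-like mean shape
#'
#' A fixed, mildly irregular 10-landmark outline standing in for a rodent
#' hemimandible in lateral view, centered and scaled to unit centroid
#' size. Any `k >= 3` is supported by sampling a jittered ellipse
#' deterministically.
#'
#' @param k number of landmarks.
#' @return `k x 2` matrix, centroid at origin, unit centroid size.
#' @export
default_mean_shape <- function(k = 10) {
  assert_that(is_count(k, 3), "need k >= 3 landmarks")
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  # deterministic jitter so landmarks are unevenly spaced / non-collinear
  jit <- 0.15 * sin(3 * th + 0.7) + 0.08 * cos(5 * th)
  r <- 1 + jit
  xy <- cbind(r * cos(th) * 1.6, r * sin(th))   # elongated, mandible-like
  xy <- sweep(xy, 2, colMeans(xy))
  xy / sqrt(sum(xy^2))
}

#' Landmark-generation model
#'
#' Parameters of the hierarchical Gaussian model behind
#' [gen_landmark_dataset()]: a mean shape, per-coordinate SDs for the
#' individual effect, the individual x side (fluctuating-asymmetry)
#' effect, the imaging (positioning) error and the digitizing error, a
#' fixed directional-asymmetry offset, and the replicate design.
#'
#' @param mean_shape `k x 2` mean configuration (unit centroid size).
#' @param n_individuals number of specimens.
#' @param sigma_ind SD of the per-individual shape effect (per coordinate).
#' @param da_vector `k x 2` fixed side difference (directional asymmetry);
#'   a scalar is expanded to a deterministic pattern of that magnitude.
#' @param sigma_fa SD of the signed left-right asymmetry per coordinate.
#' @param sigma_image SD of the per-image positioning error.
#' @param sigma_digit SD of the per-digitizing landmark error.
#' @param n_images,n_digitizings replicate design.
#' @param scale nominal centroid size (e.g. mm); all coordinates are
#'   multiplied by it.
#' @param sigma_size relative SD of the per-individual size factor
#'   (log-normal), generating body-size variation.
#' @param seed integer seed; identical model + seed gives identical data.
#' @return object of class `landmark_model`.
#' @export
landmark_model <- function(mean_shape = default_mean_shape(),
                           n_individuals = 20,
                           sigma_ind = 0.02,
                           da_vector = 0,
                           sigma_fa = 0.01,
                           sigma_image = 5e-4,
                           sigma_digit = 2e-3,
                           n_images = 2, n_digitizings = 3,
                           scale = 1, sigma_size = 0.05,
                           seed = NULL) {
  k <- nrow(mean_shape)
  assert_that(is.matrix(mean_shape) && ncol(mean_shape) == 2 && k >= 3,
              "mean_shape must be a k x 2 matrix with k >= 3")
  # non-collinearity: rank of centered shape must be 2
  assert_that(qr(sweep(mean_shape, 2, colMeans(mean_shape)))$rank == 2,
              "mean_shape landmarks are collinear")
  for (s in c(sigma_ind, sigma_fa, sigma_image, sigma_digit, sigma_size)) {
    assert_that(is.numeric(s) && length(s) == 1 && is.finite(s) && s >= 0,
                "all SDs must be single non-negative numbers")
  }
  assert_that(is_count(n_individuals, 1), "n_individuals must be >= 1")
  assert_that(is_count(n_images, 1), "n_images must be >= 1")
  assert_that(is_count(n_digitizings, 1), "n_digitizings must be >= 1")
  assert_that(is.numeric(scale) && scale > 0, "scale must be positive")
  if (length(da_vector) == 1) {
    # fixed pattern: alternating x-displacements, zero net translation
    pat <- matrix(0, k, 2)
    pat[, 1] <- rep_len(c(1, -1), k)
    pat[, 1] <- pat[, 1] - mean(pat[, 1])
    da_vector <- da_vector * pat / max(1e-12, sqrt(mean(pat[, 1]^2)))
  }
  assert_that(is.matrix(da_vector) && all(dim(da_vector) == c(k, 2)),
              "da_vector must be scalar or k x 2")
  structure(list(mean_shape = mean_shape, n_individuals = n_individuals,
                 sigma_ind = sigma_ind, da_vector = da_vector,
                 sigma_fa = sigma_fa, sigma_image = sigma_image,
                 sigma_digit = sigma_digit, n_images = n_images,
                 n_digitizings = n_digitizings, scale = scale,
                 sigma_size = sigma_size, seed = seed),
            class = "landmark_model")
}

#' Generate a replicated bilateral landmark dataset
#'
#' Simulates the full specimen x side x image x digitizing hierarchy. Per
#' individual `i`: the underlying symmetric form is
#' `mean_shape + individual effect`, the asymmetry draw is
#' `a_i ~ N(da_vector, sigma_fa^2)` per coordinate, the left side receives
#' `+a_i / 2` and the right side `-a_i / 2` before mirroring (x negated),
#' so the signed left-minus-(reflected) right difference has mean
#' `da_vector` and per-coordinate variance `sigma_fa^2`. Image effects are
#' shared by the digitizings of one photograph; digitizing noise is
#' independent per record. Everything is scaled by the individual size
#' factor times the nominal `scale`.
#'
#' @param model a [landmark_model()].
#' @param specimen_prefix prefix for specimen identifiers.
#' @param population population label stored in the metadata.
#' @return a [landmark_dataset()], plus attributes `sexes` and
#'   `size_factors` (per-specimen covariates for downstream association
#'   tests).
#' @export
gen_landmark_dataset <- function(model, specimen_prefix = "s",
                                 population = NA_character_) {
  stopifnot(inherits(model, "landmark_model"))
  k <- nrow(model$mean_shape)
  n <- model$n_individuals
  m <- model$n_images
  d <- model$n_digitizings
  with_seed(model$seed, {
    n_cfg <- n * 2 * m * d
    coords <- array(NA_real_, c(k, 2, n_cfg))
    info <- vector("list", n_cfg)
    sexes <- sample(c("F", "M"), n, replace = TRUE)
    size_f <- exp(stats::rnorm(n, 0, model$sigma_size))
    idx <- 0L
    mirror <- function(m2) { m2[, 1] <- -m2[, 1]; m2 }
    for (i in seq_len(n)) {
      ind_eff <- matrix(stats::rnorm(2 * k, 0, model$sigma_ind), k, 2)
      a_i <- model$da_vector +
        matrix(stats::rnorm(2 * k, 0, model$sigma_fa), k, 2)
      base <- model$mean_shape + ind_eff
      sides <- list(left = base + a_i / 2,
                    right = mirror(base - a_i / 2))
      for (s in names(sides)) {
        for (im in seq_len(m)) {
          img_eff <- matrix(stats::rnorm(2 * k, 0, model$sigma_image), k, 2)
          for (dg in seq_len(d)) {
            dig_eff <- matrix(stats::rnorm(2 * k, 0, model$sigma_digit),
                              k, 2)
            idx <- idx + 1L
            coords[, , idx] <-
              (sides[[s]] + img_eff + dig_eff) * model$scale * size_f[i]
            info[[idx]] <- data.frame(
              specimen = sprintf("%s%03d", specimen_prefix, i),
              population = population, side = s,
              image_rep = im, digit_rep = dg, stringsAsFactors = FALSE)
          }
        }
      }
    }
    ds <- landmark_dataset(coords, do.call(rbind, info),
                           design = list(n_images = m, n_digitizings = d))
    attr(ds, "sexes") <- setNames(sexes, sprintf("%s%03d", specimen_prefix,
                                                 seq_len(n)))
    attr(ds, "size_factors") <- setNames(size_f * model$scale,
                                         names(attr(ds, "sexes")))
    ds
  })
}

#' Genotype-generation model
#'
#' @param allele_freqs list of per-locus allele-frequency vectors, each
#'   summing to 1 (names give allele codes; unnamed vectors get codes
#'   `101, 103, ...` emulating fragment sizes).
#' @param inbreeding_f inbreeding coefficient F in `[0, 1)`.
#' @param n_individuals number of individuals.
#' @param seed integer seed.
#' @return object of class `genotype_model`.
#' @export
genotype_model <- function(allele_freqs, inbreeding_f = 0,
                           n_individuals = 30, seed = NULL) {
  assert_that(is.list(allele_freqs) && length(allele_freqs) >= 1,
              "allele_freqs must be a non-empty list")
  for (p in allele_freqs) {
    assert_that(all(p >= 0), "allele frequencies must be non-negative")
    assert_that(abs(sum(p) - 1) <= 1e-12,
                "each allele-frequency vector must sum to 1")
  }
  assert_that(is.numeric(inbreeding_f) && inbreeding_f >= 0 &&
                inbreeding_f < 1, "inbreeding_f must be in [0, 1)")
  assert_that(is_count(n_individuals, 1), "n_individuals must be >= 1")
  structure(list(allele_freqs = allele_freqs, inbreeding_f = inbreeding_f,
                 n_individuals = n_individuals, seed = seed),
            class = "genotype_model")
}

#' Generate genotypes under partial inbreeding
#'
#' Per locus and individual: with probability `F` the two alleles are
#' identical by descent (one draw from the frequency vector, duplicated),
#' otherwise they are two independent draws. This gives homozygote
#' probability `p_i^2 + F p_i (1 - p_i)` and heterozygote probability
#' `2 p_i p_j (1 - F)` — the classical inbreeding mixture, with expected
#' observed heterozygosity `(1 - F)(1 - sum p_i^2)` per locus.
#'
#' @param model a [genotype_model()].
#' @param ids optional individual identifiers.
#' @param population population label.
#' @return a [genotype_table()].
#' @export
gen_genotypes <- function(model, ids = NULL, population = "pop1") {
  stopifnot(inherits(model, "genotype_model"))
  n <- model$n_individuals
  L <- length(model$allele_freqs)
  ids <- ids %||% sprintf("ind%04d", seq_len(n))
  with_seed(model$seed, {
    arr <- array(0L, c(n, L, 2))
    for (j in seq_len(L)) {
      p <- model$allele_freqs[[j]]
      codes <- as.integer(names(p) %||% (99 + 2 * seq_along(p)))
      ibd <- stats::runif(n) < model$inbreeding_f
      a1 <- sample(codes, n, replace = TRUE, prob = p)
      a2 <- sample(codes, n, replace = TRUE, prob = p)
      a2[ibd] <- a1[ibd]
      arr[, j, 1] <- a1
      arr[, j, 2] <- a2
    }
    dimnames(arr) <- list(NULL, paste0("locus_", seq_len(L)), c("a", "b"))
    genotype_table(ids, rep(population, n), arr)
  })
}

#' Generate a spatially autocorrelated binary habitat raster
#'
#' Gaussian white noise is smoothed with a separable Gaussian kernel of
#' the given length-scale and thresholded at the empirical quantile that
#' delivers the requested habitat fraction, producing patchy,
#' forest-fragment-like rasters whose global habitat proportion matches
#' `proportion` to within one cell.
#'
#' @param proportion target habitat fraction in `[0, 1]`.
#' @param shape `c(rows, cols)`.
#' @param smoothing kernel SD in cells (0 = unsmoothed salt-and-pepper).
#' @param cell_size cell edge (m).
#' @param origin lower-left corner (m).
#' @param seed integer seed.
#' @return a [habitat_raster()].
#' @export
gen_habitat_raster <- function(proportion, shape = c(100, 100),
                               smoothing = 5, cell_size = 30,
                               origin = c(0, 0), seed = NULL) {
  assert_that(is.numeric(proportion) && proportion >= 0 && proportion <= 1,
              "proportion must be in [0, 1]")
  nr <- shape[1]; nc <- shape[2]
  with_seed(seed, {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (smoothing > 0) {
      half <- ceiling(3 * smoothing)
      kern <- stats::dnorm(-half:half, sd = smoothing)
      kern <- kern / sum(kern)
      # separable convolution with edge renormalization
      smooth1 <- function(M) {
        out <- matrix(0, nrow(M), ncol(M))
        wgt <- matrix(0, nrow(M), ncol(M))
        for (o in -half:half) {
          w <- kern[o + half + 1]
          src <- seq_len(nrow(M)) + o
          okr <- src >= 1 & src <= nrow(M)
          out[okr, ] <- out[okr, ] + w * M[src[okr], ]
          wgt[okr, ] <- wgt[okr, ] + w
        }
        out / wgt
      }
      z <- t(smooth1(t(smooth1(z))))
    }
    if (proportion <= 0) {
      g <- matrix(0L, nr, nc)
    } else if (proportion >= 1) {
      g <- matrix(1L, nr, nc)
    } else {
      thr <- stats::quantile(z, 1 - proportion, type = 1)
      g <- matrix(as.integer(z > thr), nr, nc)
    }
    habitat_raster(g, cell_size, origin)
  })
}
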