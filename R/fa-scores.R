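# Per-individual fluctuating-asymmetry indices.

# Replicate-averaged aligned configuration per specimen x side, flattened
# to 2k-vectors. Returns list(specimen, population, left, right matrices).
.side_means <- function(result) {
  info <- result$info
  if (is.null(info$population)) info$population <- NA_character_
  flat <- t(apply(result$aligned, 3, as.vector))   # n x 2k
  key <- interaction(info$specimen, info$side, drop = TRUE)
  M <- rowsum(flat, key) / as.vector(table(key))
  parts <- strsplit(rownames(M), ".", fixed = TRUE)
  spec <- vapply(parts, function(p)
    paste(p[-length(p)], collapse = "."), character(1))
  side <- vapply(parts, function(p) p[length(p)], character(1))
  specs <- intersect(unique(info$specimen),
                     intersect(spec[side == "left"], spec[side == "right"]))
  pop <- info$population[match(specs, info$specimen)]
  list(specimens = specs, populations = pop,
       left = M[match(paste(specs, "left", sep = "."), rownames(M)), ,
                drop = FALSE],
       right = M[match(paste(specs, "right", sep = "."), rownames(M)), ,
                 drop = FALSE])
}

#' Mahalanobis shape-FA score per individual
#'
#' Each specimen's asymmetry vector is the difference between its
#' replicate-averaged left and (reflected) right Procrustes configurations.
#' Directional asymmetry — the mean asymmetry across specimens — is removed,
#' and each centered deviation `d_i` is standardized by the sample
#' covariance `S` of those deviations:
#' `score_i = sqrt(d_i' S^+ d_i)`,
#' with `S^+` the Moore-Penrose pseudo-inverse restricted to eigenvalues
#' above `rank_tol` times the largest (shape space is rank-deficient, so a
#' plain inverse does not exist).
#'
#' @param result a [gpa_align()] result on a side-reflected dataset.
#' @param rank_tol relative eigenvalue cutoff for the pseudo-inverse.
#' @return data frame: `specimen`, `population`, `shape_fa`.
#' @export
mahalanobis_shape_fa <- function(result, rank_tol = 1e-10) {
  sm <- .side_means(result)
  n <- length(sm$specimens)
  assert_that(n >= 2L, "need at least 2 specimens with both sides")
  A <- sm$left - sm$right                 # asymmetry vectors
  D <- scale(A, scale = FALSE)            # remove directional asymmetry
  S <- stats::cov(D)
  eg <- eigen(S, symmetric = TRUE)
  keep <- eg$values > rank_tol * max(eg$values)
  # scores in the retained eigenbasis: whitened coordinates
  W <- D %*% eg$vectors[, keep, drop = FALSE]
  W <- sweep(W, 2, sqrt(eg$values[keep]), "/")
  data.frame(specimen = sm$specimens, population = sm$populations,
             shape_fa = sqrt(rowSums(W^2)), stringsAsFactors = FALSE)
}

#' Centroid-size FA index per individual
#'
#' The signed index is the mean over replicates of the left centroid size
#' minus the mean right centroid size (positive when the left side is
#' larger); the absolute index discards the direction. Specimens missing a
#' side are skipped and listed in the `skipped` attribute.
#'
#' @param result a [gpa_align()] result.
#' @return data frame: `specimen`, `population`, `size_fa_signed`,
#'   `size_fa_abs`.
#' @export
size_fa_index <- function(result) {
  info <- result$info
  if (is.null(info$population)) info$population <- NA_character_
  cs <- result$centroid_sizes
  agg <- tapply(cs, list(info$specimen, info$side), mean)
  assert_that(all(c("left", "right") %in% colnames(agg)),
              "both sides are required for the size FA index")
  specs <- rownames(agg)
  ok <- is.finite(agg[, "left"]) & is.finite(agg[, "right"])
  signed <- agg[ok, "left"] - agg[ok, "right"]
  out <- data.frame(
    specimen = specs[ok],
    population = info$population[match(specs[ok], info$specimen)],
    size_fa_signed = as.vector(signed),
    size_fa_abs = abs(as.vector(signed)),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- specs[!ok]
  rownames(out) <- NULL
  out
}

#' Combined per-individual FA score table
#'
#' Joins [mahalanobis_shape_fa()] and [size_fa_index()] by specimen.
#'
#' @inheritParams mahalanobis_shape_fa
#' @return data frame: `specimen`, `population`, `shape_fa`,
#'   `size_fa_signed`, `size_fa_abs`.
#' @export
fa_scores <- function(result, rank_tol = 1e-10) {
  shp <- mahalanobis_shape_fa(result, rank_tol)
  siz <- size_fa_index(result)
  merge(shp, siz[, c("specimen", "size_fa_signed", "size_fa_abs")],
        by = "specimen", all.x = TRUE, sort = FALSE)
}
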