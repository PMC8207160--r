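# Matching-symmetry preprocessing: side reflection, centroid size, and
# generalized Procrustes alignment (GPA).
#
# Internally configurations are handled as complex k-vectors (x + iy):
# centering is a column-mean subtraction, centroid size is the vector norm,
# and the least-squares *proper* rotation onto a target w is multiplication
# by exp(i * Arg(<z, w>)). Complex arithmetic guarantees determinant +1 —
# reflections can never be absorbed, which is essential when the signal of
# interest is an asymmetry.

#' Reflect one side of a bilateral dataset
#'
#' Mirrors all configurations of the chosen side about the vertical axis
#' (x-coordinates negated). Landmark order is unchanged: labels are
#' anatomical, so left/right correspondence is preserved. Applying the
#' reflection twice restores the original dataset.
#'
#' @param dataset a [landmark_dataset()].
#' @param side which side to reflect, `"right"` (default) or `"left"`.
#' @return the dataset with that side mirrored.
#' @export
reflect_side <- function(dataset, side = "right") {
  side <- match.arg(tolower(side), c("left", "right"))
  sel <- dataset$info$side == side
  dataset$coords[, 1, sel] <- -dataset$coords[, 1, sel]
  dataset
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometric size measure. It is
#' invariant to translation and rotation and scales linearly with the
#' configuration.
#'
#' @param coords `k x 2` numeric matrix, or a `k x 2 x n` array for several
#'   configurations at once.
#' @return a numeric scalar (or vector of length `n`).
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
centroid_size <- function(coords) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  assert_that(all(is.finite(coords)), "coordinates must be finite")
  cs <- apply(coords, 3, function(m) {
    m <- sweep(m, 2, colMeans(m))
    sqrt(sum(m^2))
  })
  if (length(cs) == 1L) cs[[1]] else cs
}

# k x n complex matrix from a k x 2 x n array
.as_complex <- function(coords) {
  complex(real = coords[, 1, ], imaginary = coords[, 2, ]) |>
    matrix(nrow = dim(coords)[1])
}

.from_complex <- function(z) {
  array(c(Re(z), Im(z)), dim = c(nrow(z), ncol(z), 2L)) |>
    aperm(c(1, 3, 2))
}

#' Generalized Procrustes alignment
#'
#' Iterative least-squares superimposition of all configurations: each is
#' centered, scaled to unit centroid size, and rotated (proper rotations
#' only) onto the running consensus; the consensus is then recomputed and
#' the cycle repeats until its root-mean-square change drops below `tol`.
#' For matching-symmetry analyses, call [reflect_side()] first so both
#' sides live in the same orientation.
#'
#' @param dataset a [landmark_dataset()] (already side-reflected for
#'   symmetry work).
#' @param tol convergence tolerance on the RMS change of the consensus.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return An object of class `procrustes_result`: `aligned` (k x 2 x n
#'   array of Procrustes coordinates, unit centroid size), `consensus`
#'   (k x 2, unit centroid size), `centroid_sizes` (pre-scaling, in input
#'   units), `iterations`, `converged`, plus the `info`, `k` and `design`
#'   carried over from the input.
#' @export
gpa_align <- function(dataset, tol = 1e-8, max_iter = 100L) {
  z <- .as_complex(dataset$coords)
  n <- ncol(z)
  assert_that(n >= 1L, "empty dataset")

  z <- sweep(z, 2, colMeans(z))              # center
  cs <- sqrt(colSums(Mod(z)^2))              # centroid sizes (input units)
  if (any(cs <= 0)) {
    bad <- which(cs <= 0)[1]
    stop(sprintf(
      "degenerate (all-coincident) configuration: %s %s i%d d%d",
      dataset$info$specimen[bad], dataset$info$side[bad],
      dataset$info$image_rep[bad], dataset$info$digit_rep[bad]),
      call. = FALSE)
  }
  z <- sweep(z, 2, cs, "/")                  # unit centroid size

  consensus <- z[, 1]
  consensus <- consensus / sqrt(sum(Mod(consensus)^2))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # optimal proper rotation of each column onto the consensus:
    # rotate z_j by exp(i * Arg(s_j)) with s_j = sum_k conj(z_kj) w_k
    rot <- as.vector(crossprod(Conj(z), consensus))
    z <- sweep(z, 2, exp(1i * Arg(rot)), "*")
    new_cons <- rowMeans(z)
    new_cons <- new_cons - mean(new_cons)
    new_cons <- new_cons / sqrt(sum(Mod(new_cons)^2))
    # fix the consensus' rotational gauge to the previous consensus
    new_cons <- new_cons * exp(1i * Arg(sum(Conj(new_cons) * consensus)))
    delta <- sqrt(mean(Mod(new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # final rotation pass onto the converged consensus
  rot <- as.vector(crossprod(Conj(z), consensus))
  z <- sweep(z, 2, exp(1i * Arg(rot)), "*")

  structure(list(
    aligned = .from_complex(z),
    consensus = cbind(Re(consensus), Im(consensus)),
    centroid_sizes = cs,
    iterations = iter,
    converged = converged,
    info = dataset$info, k = dataset$k, design = dataset$design),
    class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf(
    "<procrustes_result> %d configurations aligned, k = %d (%s in %d iterations)\n",
    dim(x$aligned)[3], x$k,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Export aligned coordinates and centroid sizes
#'
#' @param result a [gpa_align()] result.
#' @return data frame: one row per configuration, metadata columns,
#'   `centroid_size`, then `x1, y1, ..., xk, yk` Procrustes coordinates.
#' @export
procrustes_long <- function(result) {
  n <- dim(result$aligned)[3]
  flat <- t(apply(result$aligned, 3, function(m) as.vector(t(m))))
  colnames(flat) <- as.vector(t(outer(seq_len(result$k), c("x", "y"),
                                      function(i, a) paste0(a, i))))
  cbind(result$info,
        data.frame(centroid_size = result$centroid_sizes), flat)
}
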