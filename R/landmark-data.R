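#' Replicated bilateral landmark dataset
#'
#' Container for 2-D landmark configurations keyed by specimen, side, image
#' replicate and digitizing replicate — the design used to separate
#' fluctuating asymmetry from measurement error. Coordinates are stored as a
#' `k x 2 x n` array in configuration order; metadata lives in a parallel
#' data frame.
#'
#' @param coords numeric array `k x 2 x n` (or a list of `k x 2` matrices).
#' @param info data frame with one row per configuration and columns
#'   `specimen`, `side` (`"left"`/`"right"`), `image_rep`, `digit_rep`, and
#'   optionally `population` (defaults to `NA`).
#' @param design optional list `list(n_images =, n_digitizings =)` declaring
#'   the intended replicate design; inferred from the data when omitted.
#'
#' @return An object of class `landmark_dataset` with elements `coords`,
#'   `info`, `k` and `design`.
#' @export
landmark_dataset <- function(coords, info, design = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    k <- nrow(coords[[1]])
    coords <- array(unlist(coords), dim = c(k, 2L, length(coords)))
  }
  assert_that(is.array(coords) && length(dim(coords)) == 3L &&
                dim(coords)[2] == 2L,
              "coords must be a k x 2 x n array")
  assert_that(all(is.finite(coords)), "coordinates must be finite")
  n <- dim(coords)[3]
  assert_that(is.data.frame(info) && nrow(info) == n,
              "info must have one row per configuration")
  needed <- c("specimen", "side", "image_rep", "digit_rep")
  assert_that(all(needed %in% names(info)),
              paste("info needs columns:", paste(needed, collapse = ", ")))
  if (!"population" %in% names(info)) info$population <- NA_character_
  info$side <- tolower(as.character(info$side))
  assert_that(all(info$side %in% c("left", "right")),
              "side must be 'left' or 'right'")
  key <- with(info, paste(specimen, side, image_rep, digit_rep, sep = "|"))
  if (anyDuplicated(key)) {
    stop("duplicate configuration key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(design)) {
    design <- list(n_images = max(info$image_rep),
                   n_digitizings = max(info$digit_rep))
  }
  structure(list(coords = coords, info = info, k = dim(coords)[1],
                 design = design),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf(
    "<landmark_dataset> %d configurations, k = %d landmarks\n",
    dim(x$coords)[3], x$k))
  cat(sprintf("  specimens: %d | design: %d image(s) x %d digitizing(s)\n",
              length(unique(x$info$specimen)),
              x$design$n_images, x$design$n_digitizings))
  invisible(x)
}

#' Assemble and audit a landmark dataset against a replicate design
#'
#' Checks completeness of the specimen x side x image x digitizing grid.
#' Specimens missing an entire side are flagged for exclusion from symmetry
#' analyses; missing replicates are tolerated (the ANOVA is fitted on the
#' observed, possibly unbalanced, design) but reported.
#'
#' @param dataset a [landmark_dataset()].
#' @param design list with `n_images` and `n_digitizings`.
#' @return A list with `dataset` (configurations from one-sided specimens
#'   removed), `complete` (logical), `excluded_specimens`,
#'   `missing_replicates` (data frame of absent specimen/side/replicate
#'   combinations).
#' @export
assemble_dataset <- function(dataset, design = dataset$design) {
  info <- dataset$info
  specs <- unique(info$specimen)
  sides_of <- function(s) unique(info$side[info$specimen == s])
  excluded <- specs[vapply(specs, function(s)
    length(sides_of(s)) < 2L, logical(1))]

  grid <- expand.grid(specimen = setdiff(specs, excluded),
                      side = c("left", "right"),
                      image_rep = seq_len(design$n_images),
                      digit_rep = seq_len(design$n_digitizings),
                      stringsAsFactors = FALSE)
  key_obs <- with(info, paste(specimen, side, image_rep, digit_rep))
  key_exp <- with(grid, paste(specimen, side, image_rep, digit_rep))
  missing <- grid[!(key_exp %in% key_obs), , drop = FALSE]

  keep <- !(info$specimen %in% excluded)
  out <- landmark_dataset(dataset$coords[, , keep, drop = FALSE],
                          info[keep, , drop = FALSE], design)
  list(dataset = out,
       complete = length(excluded) == 0L && nrow(missing) == 0L,
       excluded_specimens = excluded,
       missing_replicates = missing)
}

#' Export a landmark dataset as a long-format table
#'
#' One row per configuration x landmark, suitable for CSV export.
#'
#' @param dataset a [landmark_dataset()].
#' @return data frame with metadata columns plus `landmark`, `x`, `y`.
#' @export
landmarks_long <- function(dataset) {
  n <- dim(dataset$coords)[3]
  k <- dataset$k
  info <- dataset$info[rep(seq_len(n), each = k), , drop = FALSE]
  info$landmark <- rep(seq_len(k), n)
  info$x <- as.vector(dataset$coords[, 1, ])
  info$y <- as.vector(dataset$coords[, 2, ])
  rownames(info) <- NULL
  info
}
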