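# Scale-of-effect radii and buffer habitat amount on binary rasters.

#' Binary habitat raster
#'
#' A rows x cols grid of 0/1 cells (1 = habitat) on a planar metric
#' coordinate system. Row 1 is the southernmost row: the center of cell
#' `[r, c]` sits at `origin + ((c - 0.5), (r - 0.5)) * cell_size`.
#'
#' @param grid integer/logical matrix of 0/1 values.
#' @param cell_size cell edge length in meters.
#' @param origin `(x, y)` of the lower-left corner of the grid, meters.
#' @return object of class `habitat_raster`.
#' @export
habitat_raster <- function(grid, cell_size, origin = c(0, 0)) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  assert_that(all(grid %in% c(0L, 1L)), "grid cells must be 0 or 1")
  assert_that(is.numeric(cell_size) && cell_size > 0,
              "cell_size must be positive")
  structure(list(grid = grid, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf(
    "<habitat_raster> %d x %d cells of %g m (habitat fraction %.3f)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, mean(x$grid)))
  invisible(x)
}

#' Read / write a habitat raster as a plain-text grid
#'
#' Simple ASCII format: a five-line header (`nrows`, `ncols`, `xllcorner`,
#' `yllcorner`, `cellsize`) followed by the grid written north-to-south
#' (top row first), space-separated.
#'
#' @param path file path.
#' @return a [habitat_raster()] (for `read_habitat_raster`).
#' @export
read_habitat_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lapply(strsplit(lines[1:5], "[[:space:]]+"), function(v)
    list(key = tolower(v[1]), val = as.numeric(v[2])))
  vals <- setNames(vapply(hdr, `[[`, numeric(1), "val"),
                   vapply(hdr, `[[`, character(1), "key"))
  rows <- lapply(strsplit(trimws(lines[-(1:5)]), "[[:space:]]+"),
                 as.integer)
  g <- do.call(rbind, rows)
  g <- g[nrow(g):1, , drop = FALSE]   # stored top-first; row 1 = south
  habitat_raster(g, vals[["cellsize"]],
                 c(vals[["xllcorner"]], vals[["yllcorner"]]))
}

#' @rdname read_habitat_raster
#' @param raster a [habitat_raster()].
#' @export
write_habitat_raster <- function(raster, path) {
  g <- raster$grid[nrow(raster$grid):1, , drop = FALSE]
  writeLines(c(
    paste("nrows", nrow(g)), paste("ncols", ncol(g)),
    paste("xllcorner", format(raster$origin[1], digits = 15)),
    paste("yllcorner", format(raster$origin[2], digits = 15)),
    paste("cellsize", format(raster$cell_size, digits = 15)),
    apply(g, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Scale of effect from home-range area
#'
#' Converts a home-range area to the candidate landscape radii over which
#' habitat amount is expected to influence a population: the home range's
#' linear dimension is `LD = sqrt(HR)`, the maximum dispersal distance is
#' `MDD = 40 * LD` (the allometric dispersal/home-range ratio for small
#' mammals), and the scale-of-effect band spans 30% to 50% of MDD. All
#' derived quantities are computed from the unrounded linear distance.
#'
#' @param home_range_m2 home-range area(s) in square meters.
#' @return data frame: `home_range_m2`, `linear_distance`, `mdd`,
#'   `scale_min` (30% MDD), `scale_max` (50% MDD), in meters.
#' @export
#' @examples
#' scale_effect(2200)   # LD 46.9, MDD 1876.2, band 562.8 - 938.1 m
scale_effect <- function(home_range_m2) {
  assert_that(is.numeric(home_range_m2) && all(home_range_m2 > 0),
              "home range must be positive")
  ld <- sqrt(home_range_m2)
  mdd <- 40 * ld
  data.frame(home_range_m2 = home_range_m2,
             linear_distance = ld, mdd = mdd,
             scale_min = 0.30 * mdd, scale_max = 0.50 * mdd)
}

#' Percentage habitat within a circular buffer
#'
#' Habitat amount around a site: the percentage of raster cells whose
#' center lies within `radius_m` of the site that are habitat. Cells
#' falling outside the raster extent are excluded from both numerator and
#' denominator; if more than 1% of the buffer area lies off-raster a
#' `coverage` warning attribute is attached.
#'
#' @param raster a [habitat_raster()].
#' @param site_xy numeric `(x, y)` site coordinates, meters.
#' @param radius_m buffer radius, meters.
#' @return percentage in `[0, 100]`, with attributes `n_cells` (cells in
#'   the buffer) and `coverage` (fraction of the buffer area on-raster).
#' @export
habitat_amount <- function(raster, site_xy, radius_m) {
  assert_that(is.numeric(radius_m) && radius_m > 0,
              "radius must be positive")
  g <- raster$grid
  cs <- raster$cell_size
  # restrict to the bounding box of the circle
  cx <- (site_xy[1] - raster$origin[1]) / cs
  cy <- (site_xy[2] - raster$origin[2]) / cs
  r_cells <- radius_m / cs
  c_lo <- max(1, floor(cx - r_cells))
  c_hi <- min(ncol(g), ceiling(cx + r_cells) + 1)
  r_lo <- max(1, floor(cy - r_cells))
  r_hi <- min(nrow(g), ceiling(cy + r_cells) + 1)
  if (c_lo > c_hi || r_lo > r_hi) {
    stop("buffer lies entirely off the raster", call. = FALSE)
  }
  cols <- c_lo:c_hi
  rows <- r_lo:r_hi
  xc <- raster$origin[1] + (cols - 0.5) * cs
  yc <- raster$origin[2] + (rows - 0.5) * cs
  d2 <- outer(yc - site_xy[2], xc - site_xy[1],
              function(dy, dx) dy^2 + dx^2)
  inside <- d2 <= radius_m^2
  n_in <- sum(inside)
  if (n_in == 0L) stop("buffer contains no cell centers", call. = FALSE)
  hab <- sum(g[rows, cols, drop = FALSE][inside])
  pct <- 100 * hab / n_in
  # coverage: in-circle lattice centers on the raster vs on the unbounded
  # lattice (so coarse-cell discretization is not mistaken for data loss)
  vcols <- floor(cx - r_cells):ceiling(cx + r_cells + 1)
  vrows <- floor(cy - r_cells):ceiling(cy + r_cells + 1)
  vd2 <- outer((vrows - 0.5) - cy, (vcols - 0.5) - cx,
               function(dy, dx) dy^2 + dx^2)
  n_virtual <- sum(vd2 <= r_cells^2)
  coverage <- min(1, n_in / n_virtual)
  if (coverage < 0.99) {
    warning(sprintf(
      "only %.1f%% of the buffer falls on the raster", 100 * coverage))
  }
  structure(pct, n_cells = n_in, coverage = coverage)
}

#' Habitat amount for several sites and radii
#'
#' @param rasters a single [habitat_raster()] or a named list, one per
#'   site.
#' @param sites data frame with `site_id`, `x`, `y`.
#' @param radii numeric vector of buffer radii (m).
#' @return data frame: one row per site, one `r<radius>m` column per
#'   radius.
#' @export
habitat_amount_table <- function(rasters, sites, radii) {
  one <- inherits(rasters, "habitat_raster")
  out <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  for (r in radii) {
    out[[sprintf("r%gm", r)]] <- vapply(seq_len(nrow(sites)), function(i) {
      ras <- if (one) rasters else rasters[[sites$site_id[i]]]
      as.numeric(habitat_amount(ras, c(sites$x[i], sites$y[i]), r))
    }, numeric(1))
  }
  out
}
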