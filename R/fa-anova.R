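# Procrustes ANOVA for matching symmetry, and its scalar (centroid-size)
# counterpart.
#
# The linear model, per Procrustes coordinate, is
#   y = individual + side + individual:side + image(ind, side) + digitizing
# where "individual:side" carries the fluctuating asymmetry, "side" the
# directional asymmetry, the image stratum the positioning/photography
# error, and the digitizing residual the landmark-placement error. Sums of
# squares are sequential (Type I) over that nested hierarchy, computed for
# all coordinates at once and summed, so unbalanced replicate structures
# are handled as observed. For shape, structural degrees of freedom are
# multiplied by the shape-space dimension 2k - 4 (2-D configurations lose
# 2 translations, 1 rotation and 1 scale to superimposition).
#
# F ratios follow the mixed-model chain: individual and side are tested
# against individual:side; individual:side against the image stratum; the
# image stratum against the digitizing residual.

# Sequential SS over the ordered design blocks. Y: n x p response matrix.
#
# Every stratum except "side" is a factor partition, so its projection is a
# group-mean operation (rowsum); "side" contributes one contrast, fitted
# after "individual" by Frisch-Waugh (regress the individual-centered side
# indicator against the individual-centered responses). This is exact
# sequential least squares on unbalanced designs and orders of magnitude
# faster than a dummy-matrix QR.
.nested_ss <- function(Y, info) {
  n <- nrow(Y)
  ind  <- factor(info$specimen)
  cell <- interaction(ind, info$side, drop = TRUE)
  img  <- interaction(cell, info$image_rep, drop = TRUE)

  sqtot <- sum(Y^2)
  part_rss <- function(f) {
    # residual SS after projecting each column on the partition of f
    M <- rowsum(Y, f)
    cnt <- as.vector(table(f))
    sqtot - sum(M^2 / cnt)
  }
  rss_grand <- sqtot - n * sum(colMeans(Y)^2)
  rss_ind <- part_rss(ind)
  # side contrast after individual (Frisch-Waugh on the centered indicator)
  s <- as.numeric(info$side == "right")
  ind_mean <- function(v) ave(v, ind)
  s_t <- s - ind_mean(s)
  ssq_s <- sum(s_t^2)
  if (ssq_s > 1e-12 * n) {
    ss_side <- sum((crossprod(s_t, Y - apply(Y, 2, ind_mean)))^2) / ssq_s
    df_side <- 1L
  } else {
    ss_side <- 0
    df_side <- 0L
  }
  rss_side <- rss_ind - ss_side
  rss_cell <- part_rss(cell)
  rss_img <- part_rss(img)

  df_ind <- nlevels(ind) - 1L
  df_cell <- (nlevels(cell) - 1L) - df_ind - df_side
  df_img <- nlevels(img) - nlevels(cell)
  df_res <- n - nlevels(img)

  list(ss = c(rss_grand - rss_ind, ss_side, rss_side - rss_cell,
              rss_cell - rss_img, rss_img),
       df = c(df_ind, df_side, df_cell, df_img, df_res),
       effects = c("individual", "side", "individual:side", "error1",
                   "residual"))
}

.anova_table <- function(Y, info, df_mult, trait) {
  dec <- .nested_ss(Y, info)
  eff <- dec$effects
  SS <- pmax(dec$ss, 0)   # guard against floating-point dust below zero
  df <- dec$df * c(df_mult, df_mult, df_mult, df_mult, df_mult)
  MS <- ifelse(df > 0, SS / df, NA_real_)

  # denominator chain; fall back to the next stratum when one has no df
  denom_of <- c(individual = "individual:side",
                side = "individual:side",
                `individual:side` = "error1",
                error1 = "residual",
                residual = NA)
  Fv <- pv <- rep(NA_real_, 5)
  denom_used <- rep(NA_character_, 5)
  for (i in 1:4) {
    d <- denom_of[[eff[i]]]
    while (!is.na(d) && (df[match(d, eff)] == 0 ||
                         !is.finite(MS[match(d, eff)]))) {
      d <- denom_of[[d]]
    }
    if (is.na(d)) next
    j <- match(d, eff)
    Fv[i] <- MS[i] / MS[j]
    pv[i] <- stats::pf(Fv[i], df[i], df[j], lower.tail = FALSE)
    denom_used[i] <- d
  }
  out <- data.frame(effect = eff, SS = SS, df = df, MS = MS, F = Fv,
                    p = pv, denominator = denom_used,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "df_multiplier") <- df_mult
  class(out) <- c("fa_anova", "data.frame")
  out
}

#' @export
print.fa_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Nested %s ANOVA (df multiplier %d)\n",
              attr(x, "trait"), attr(x, "df_multiplier")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

.check_two_sides <- function(info) {
  assert_that(length(unique(info$side)) == 2L,
              "both sides are required (only one side present)")
  both <- tapply(info$side, info$specimen,
                 function(s) length(unique(s)) == 2L)
  assert_that(sum(both) >= 2L,
              "need at least 2 individuals with both sides")
}

#' Procrustes ANOVA for shape asymmetry
#'
#' Partitions the squared Procrustes-coordinate deviations (summed over all
#' 2k coordinates) into individual, side (directional asymmetry),
#' individual x side (fluctuating asymmetry), image-replicate and
#' digitizing-replicate strata. Degrees of freedom are the structural df of
#' the observed design multiplied by 2k - 4. Goodall-style F statistics are
#' referred to the F distribution.
#'
#' @param result a [gpa_align()] result on a side-reflected dataset.
#' @return an `fa_anova` data frame (effect, SS, df, MS, F, p, denominator).
#' @export
procrustes_anova <- function(result) {
  .check_two_sides(result$info)
  Y <- t(apply(result$aligned, 3, as.vector))
  .anova_table(Y, result$info, df_mult = 2L * result$k - 4L,
               trait = "shape (Procrustes)")
}

#' Centroid-size ANOVA for size asymmetry
#'
#' The same nested design as [procrustes_anova()], fitted to the scalar
#' centroid size of each configuration (df multiplier 1).
#'
#' @param result a [gpa_align()] result.
#' @return an `fa_anova` data frame.
#' @export
size_anova <- function(result) {
  .check_two_sides(result$info)
  .anova_table(matrix(result$centroid_sizes, ncol = 1), result$info,
               df_mult = 1L, trait = "centroid size")
}

#' Fluctuating-asymmetry detection rule
#'
#' FA is declared present when the individual x side interaction is
#' significant (`p < p_threshold`) *and* its F value exceeds `f_ratio`
#' times the F of the measurement-error stratum — i.e. the asymmetry signal
#' stands well clear of measurement noise.
#'
#' @param anova an `fa_anova` table.
#' @param p_threshold significance level for the interaction (default .05).
#' @param f_ratio required F(interaction) / F(error) multiple (default 10).
#' @return list with `detected`, and the individual criteria
#'   `significant`, `exceeds_error` plus the quantities used.
#' @export
detect_fa <- function(anova, p_threshold = 0.05, f_ratio = 10) {
  need <- c("individual:side", "error1")
  assert_that(all(need %in% anova$effect),
              "ANOVA table lacks interaction or error rows")
  int <- anova[anova$effect == "individual:side", ]
  err <- anova[anova$effect == "error1", ]
  sig <- is.finite(int$p) && int$p < p_threshold
  exceeds <- is.finite(int$F) && is.finite(err$F) &&
    int$F > f_ratio * err$F
  list(detected = sig && exceeds, significant = sig,
       exceeds_error = exceeds,
       F_interaction = int$F, p_interaction = int$p, F_error = err$F)
}
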