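# Whole-study synthesis: coherent landmark datasets, genotype tables,
# habitat rasters and site coordinates for a multi-site design.

#' Build a synthetic study scenario
#'
#' Describes a multi-site study in the mold of the Atlantic-forest
#' water-rat system: per-site habitat proportion and sample size, a
#' replicate design for the landmark data, a rule linking habitat amount
#' to the developmental-noise SD (`sigma_fa`), and population-genetic
#' parameters. Defaults reproduce that system's structure: 8 sites with
#' habitat cover spanning ~19-100%, 8-15 specimens each, 10 landmarks x 2
#' sides x 2 images x 3 digitizings, and 7 microsatellite loci with 5
#' equifrequent alleles.
#'
#' The default `fa_rule` makes the asymmetry SD decrease linearly with
#' habitat proportion `h`: `sigma_fa = fa_base + fa_slope * (1 - h)`.
#' Setting `fa_slope = 0` gives the null scenario (no habitat effect), the
#' reference point for type-I-error checks.
#'
#' @param habitat_props per-site habitat proportions in `[0, 1]`.
#' @param n_per_site specimens per site.
#' @param fa_base,fa_slope parameters of the default FA-variance rule.
#' @param fa_rule optional function `h -> sigma_fa` overriding the linear
#'   rule.
#' @param inbreeding_f per-site inbreeding coefficient (recycled).
#' @param n_loci,n_alleles microsatellite design.
#' @param raster_shape,cell_size,smoothing habitat-raster parameters.
#' @param k,n_images,n_digitizings landmark design.
#' @param sigma_ind,sigma_image,sigma_digit,da_mag,scale,sigma_size
#'   landmark-model noise parameters (see [landmark_model()]).
#' @return list of class `study_scenario`.
#' @export
study_scenario <- function(
    habitat_props = c(0.1886, 0.2815, 0.3926, 0.6625,
                      0.7102, 0.7322, 0.9959, 1.0),
    n_per_site = c(8, 9, 11, 11, 15, 11, 13, 9),
    fa_base = 0.008, fa_slope = 0.008, fa_rule = NULL,
    inbreeding_f = 0.05,
    n_loci = 7, n_alleles = 5,
    raster_shape = c(100, 100), cell_size = 30, smoothing = 1.5,
    k = 10, n_images = 2, n_digitizings = 3,
    sigma_ind = 0.02, sigma_image = 5e-4, sigma_digit = 2e-3,
    da_mag = 0.003, scale = 20, sigma_size = 0.05) {
  n_sites <- length(habitat_props)
  assert_that(n_sites >= 1, "need at least one site")
  assert_that(all(habitat_props >= 0 & habitat_props <= 1),
              "habitat proportions must be in [0, 1]")
  n_per_site <- rep_len(n_per_site, n_sites)
  inbreeding_f <- rep_len(inbreeding_f, n_sites)
  # force now so the closure's environment is fixed at creation time
  # (matters for configuration fingerprinting)
  force(fa_base); force(fa_slope)
  rule <- fa_rule %||% function(h) fa_base + fa_slope * (1 - h)
  structure(list(
    habitat_props = habitat_props, n_per_site = n_per_site,
    fa_rule = rule, inbreeding_f = inbreeding_f,
    n_loci = n_loci, n_alleles = n_alleles,
    raster_shape = raster_shape, cell_size = cell_size,
    smoothing = smoothing,
    k = k, n_images = n_images, n_digitizings = n_digitizings,
    sigma_ind = sigma_ind, sigma_image = sigma_image,
    sigma_digit = sigma_digit, da_mag = da_mag, scale = scale,
    sigma_size = sigma_size), class = "study_scenario")
}

#' Generate a full synthetic study
#'
#' Expands a [study_scenario()] into site-labelled landmark data, genotype
#' tables, habitat rasters and site coordinates. One master seed drives
#' everything; each site uses fixed-offset sub-streams, so sites are
#' reproducible independently of one another.
#'
#' @param scenario a [study_scenario()].
#' @param seed master integer seed.
#' @return list of class `study_bundle`: `sites` (data frame with
#'   `site_id`, `x`, `y`, `habitat_prop`, `n`, `sigma_fa`), `landmarks`
#'   (one combined [landmark_dataset()]), `covariates` (per-specimen sex
#'   and body size), `genotypes` ([genotype_table()]), `rasters` (named
#'   list of [habitat_raster()]), `scenario`, `seed`.
#' @export
gen_study <- function(scenario = study_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "study_scenario"))
  n_sites <- length(scenario$habitat_props)
  site_ids <- sprintf("P%d", seq_len(n_sites))
  mean_shape <- default_mean_shape(scenario$k)
  freqs <- replicate(scenario$n_loci,
                     rep(1 / scenario$n_alleles, scenario$n_alleles),
                     simplify = FALSE)

  datasets <- vector("list", n_sites)
  genos <- vector("list", n_sites)
  rasters <- vector("list", n_sites)
  covs <- vector("list", n_sites)
  sigma_fas <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    h <- scenario$habitat_props[i]
    sigma_fas[i] <- scenario$fa_rule(h)
    lm_model <- landmark_model(
      mean_shape = mean_shape,
      n_individuals = scenario$n_per_site[i],
      sigma_ind = scenario$sigma_ind, da_vector = scenario$da_mag,
      sigma_fa = sigma_fas[i], sigma_image = scenario$sigma_image,
      sigma_digit = scenario$sigma_digit,
      n_images = scenario$n_images,
      n_digitizings = scenario$n_digitizings,
      scale = scenario$scale, sigma_size = scenario$sigma_size,
      seed = derive_seed(seed, i, 0L))
    ds <- gen_landmark_dataset(lm_model,
                               specimen_prefix = paste0(site_ids[i], ".s"),
                               population = site_ids[i])
    covs[[i]] <- data.frame(
      specimen = names(attr(ds, "sexes")),
      population = site_ids[i],
      sex = unname(attr(ds, "sexes")),
      body_size = unname(attr(ds, "size_factors")),
      stringsAsFactors = FALSE)
    datasets[[i]] <- ds
    gt_model <- genotype_model(freqs, scenario$inbreeding_f[i],
                               scenario$n_per_site[i],
                               seed = derive_seed(seed, i, 500L))
    genos[[i]] <- gen_genotypes(gt_model, ids = covs[[i]]$specimen,
                                population = site_ids[i])
    rasters[[i]] <- gen_habitat_raster(
      h, scenario$raster_shape, scenario$smoothing, scenario$cell_size,
      seed = derive_seed(seed, i, 700L))
  }
  names(rasters) <- site_ids

  coords <- do.call(function(...) {
    arrs <- list(...)
    array(unlist(arrs), dim = c(scenario$k, 2,
                                sum(vapply(arrs, function(a) dim(a)[3],
                                           integer(1)))))
  }, lapply(datasets, `[[`, "coords"))
  info <- do.call(rbind, lapply(datasets, `[[`, "info"))
  landmarks <- landmark_dataset(
    coords, info, design = list(n_images = scenario$n_images,
                                n_digitizings = scenario$n_digitizings))

  geno_arr <- do.call(abind_3d, lapply(genos, `[[`, "alleles"))
  genotypes <- genotype_table(
    unlist(lapply(genos, `[[`, "ids")),
    unlist(lapply(genos, `[[`, "populations")),
    geno_arr)

  ext <- scenario$raster_shape * scenario$cell_size
  sites <- data.frame(
    site_id = site_ids,
    x = ext[2] / 2, y = ext[1] / 2,          # site at raster center
    habitat_prop = scenario$habitat_props,
    n = scenario$n_per_site, sigma_fa = sigma_fas,
    stringsAsFactors = FALSE)

  structure(list(sites = sites, landmarks = landmarks,
                 covariates = do.call(rbind, covs),
                 genotypes = genotypes, rasters = rasters,
                 scenario = scenario, seed = seed),
            class = "study_bundle")
}

# row-bind 3-D arrays along the first margin (shared dims 2 and 3)
abind_3d <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(arrs[[1]][0], c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  dimnames(out) <- list(NULL, dimnames(arrs[[1]])[[2]],
                        dimnames(arrs[[1]])[[3]])
  out
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_bundle> %d sites, %d specimens, seed %s\n",
    nrow(x$sites), length(unique(x$landmarks$info$specimen)),
    format(x$seed)))
  invisible(x)
}
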