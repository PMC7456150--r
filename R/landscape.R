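#' Configuration for the synthetic landscape generator
#'
#' Bundles and validates the parameters of [generate_landscape()]. Defaults
#' describe a 25 million km2 northern domain of 10-km cells with a
#' latitudinal MAAT gradient spanning -25 to +10 degrees C, a peat-fraction
#' profile peaking in the boreal zone, and peat depths from a truncated
#' normal with a 40-cm floor (the organic-depth threshold that defines a
#' peatland). The post-truncation depth mean equals `depth_mean`: the
#' underlying normal mean is solved internally so the floor does not bias
#' the sampled mean.
#'
#' @param nrow,ncol grid shape (rows run north to south).
#' @param cell_area cell area, km2.
#' @param maat_range coldest and warmest MAAT of the latitudinal gradient,
#'   degrees C.
#' @param maat_noise_sd cell-level MAAT noise, degrees C.
#' @param depth_mean,depth_sd target mean and sd of peat depth, cm.
#' @param depth_floor minimum organic depth defining peat presence, cm.
#' @param peat_scale,peat_maat_peak,peat_maat_width peat-fraction climate
#'   profile: `peat_scale * exp(-(MAAT - peak)^2 / (2 width^2))`, modulated
#'   by lognormal noise (`peat_noise_sdlog`) and thresholded at
#'   `peat_min_fraction`.
#' @param peat_noise_sdlog,peat_min_fraction see above.
#' @param curve_params [permafrost_params()] used to generate permafrost
#'   fraction from MAAT.
#' @param pf_noise_sd additive noise on the generated permafrost fraction
#'   (clipped back to `[0, 1]`).
#' @param bd_median,bd_sdlog lognormal bulk-density parameters, g cm-3.
#' @param oc_mean,oc_sd organic-carbon content (weight %), truncated to
#'   `[10, 60]`.
#' @param n_mean,n_sd total nitrogen content (weight %), truncated to a
#'   0.2 % floor.
#' @param storage_params [storage_params()] used for per-cell storages.
#' @param tundra_maat,boreal_maat biome class cutoffs: tundra at or below
#'   `tundra_maat`, boreal up to `boreal_maat`, otherwise "other".
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   landscapes.
#' @return an object of class `"synth_config"` (a validated list).
#' @export
synth_config <- function(nrow = 500, ncol = 500, cell_area = 100,
                         maat_range = c(-25, 10), maat_noise_sd = 2,
                         depth_mean = 249, depth_sd = 97, depth_floor = 40,
                         peat_scale = 0.31, peat_maat_peak = -3,
                         peat_maat_width = 7, peat_noise_sdlog = 0.6,
                         peat_min_fraction = 0.01,
                         curve_params = permafrost_params("central"),
                         pf_noise_sd = 0.05,
                         bd_median = 0.09, bd_sdlog = 0.35,
                         oc_mean = 45, oc_sd = 10,
                         n_mean = 1.5, n_sd = 0.8,
                         storage_params = NULL,
                         tundra_maat = -8, boreal_maat = 2,
                         seed = 1L) {
  if (nrow < 1 || ncol < 1) stop("grid shape must be positive")
  for (s in c(maat_noise_sd, depth_sd, pf_noise_sd, peat_noise_sdlog,
              oc_sd, n_sd, bd_sdlog))
    if (s < 0) stop("standard deviations must be non-negative")
  if (depth_mean <= depth_floor)
    stop("'depth_mean' must exceed 'depth_floor'")
  stopifnot(inherits(curve_params, "permafrost_params"))
  cfg <- as.list(environment())
  if (is.null(cfg$storage_params)) cfg$storage_params <- storage_params()
  structure(cfg, class = "synth_config")
}

# Inverse-CDF sampler for a normal truncated below at `floor`; `mean` is
# the target post-truncation mean (underlying mean solved by uniroot).
rtnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(max(mean, floor), n))
  trunc_mean <- function(mu) {
    a <- (floor - mu) / sd
    mu + sd * stats::dnorm(a) /
      stats::pnorm(a, lower.tail = FALSE) - mean
  }
  mu0 <- stats::uniroot(trunc_mean, c(floor - 3 * sd, mean + sd))$root
  plo <- stats::pnorm((floor - mu0) / sd)
  mu0 + sd * stats::qnorm(plo + stats::runif(n) * (1 - plo))
}

# Two-sided truncated normal via inverse CDF.
rtnorm_ab <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(plo + stats::runif(n) * (phi - plo))
}

#' Generate a synthetic peatland landscape
#'
#' Draws a gridded landscape with per-cell MAAT, peatland areal fraction,
#' permafrost fraction (evaluated from the configured equilibrium curve
#' plus noise, zeroed where MAAT exceeds +1 degree C), peat depth, C and N
#' storages, biome class and minerotrophic/ombrotrophic type shares.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `"landscape_grid"`: a list with `nrow`,
#'   `ncol`, `cell_area` (km2) and per-cell vectors `maat` (degrees C),
#'   `peat_fraction`, `permafrost_fraction`, `peat_depth` (cm; 0 where no
#'   peat), `c_storage` (kg C m-2), `n_storage` (kg N m-2), `biome_class`,
#'   `minero_frac`, `ombro_frac`. Cell order is column-major over the
#'   (nrow x ncol) grid.
#' @examples
#' grid <- generate_landscape(synth_config(nrow = 40, ncol = 40, seed = 7))
#' grid
#' @export
generate_landscape <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$nrow * config$ncol

  lat <- seq(config$maat_range[1], config$maat_range[2],
             length.out = config$nrow)
  maat <- rep(lat, times = config$ncol) +
    stats::rnorm(n, 0, config$maat_noise_sd)

  prof <- config$peat_scale *
    exp(-(maat - config$peat_maat_peak)^2 / (2 * config$peat_maat_width^2))
  noise <- stats::rlnorm(n, -0.5 * config$peat_noise_sdlog^2,
                         config$peat_noise_sdlog)
  peat <- pmin(prof * noise, 1)
  peat[peat < config$peat_min_fraction] <- 0

  pf <- permafrost_fraction(maat, config$curve_params)
  if (config$pf_noise_sd > 0)
    pf <- pf + stats::rnorm(n, 0, config$pf_noise_sd)
  pf <- pmin(pmax(pf, 0), 1)
  pf[maat > 1] <- 0

  depth <- numeric(n)
  has_peat <- peat > 0
  depth[has_peat] <- rtnorm_floor(sum(has_peat), config$depth_mean,
                                  config$depth_sd, config$depth_floor)

  sp <- config$storage_params
  c_st <- predict_storage(depth, sp, what = "c")
  n_st <- pf  * predict_storage(depth, sp, what = "n", permafrost = TRUE) +
    (1 - pf) * predict_storage(depth, sp, what = "n", permafrost = FALSE)
  c_st[!has_peat] <- 0
  n_st[!has_peat] <- 0

  biome <- ifelse(maat <= config$tundra_maat, "tundra",
                  ifelse(maat <= config$boreal_maat, "boreal", "other"))

  grid <- structure(list(
    nrow = config$nrow, ncol = config$ncol, cell_area = config$cell_area,
    maat = maat, peat_fraction = peat, permafrost_fraction = pf,
    peat_depth = depth, c_storage = c_st, n_storage = n_st,
    biome_class = biome,
    minero_frac = rep(NA_real_, n), ombro_frac = rep(NA_real_, n)),
    class = "landscape_grid")
  partition_peatland_types(grid)
}

#' @export
print.landscape_grid <- function(x, ...) {
  a <- x$cell_area * x$peat_fraction
  cat(sprintf("Synthetic peatland landscape: %d x %d cells of %g km2\n",
              x$nrow, x$ncol, x$cell_area))
  cat(sprintf("  peat area %.2f Mkm2, permafrost peat area %.2f Mkm2\n",
              sum(a) / 1e6, sum(a * x$permafrost_fraction) / 1e6))
  cat(sprintf("  MAAT %.1f to %.1f C; mean peat depth %.0f cm\n",
              min(x$maat), max(x$maat),
              stats::weighted.mean(x$peat_depth, a)))
  invisible(x)
}

#' Per-core carbon (or nitrogen) storage from depth, bulk density and
#' element content
#'
#' `storage = depth_cm * bulk_density_g_cm3 * content_pct / 100 * 10`,
#' in kg per m2 (the factor 10 converts g cm-2 to kg m-2).
#'
#' @param depth_cm peat depth, cm.
#' @param bulk_density dry bulk density, g cm-3.
#' @param content_pct element content, weight percent.
#' @return storage in kg m-2.
#' @examples
#' core_storage(100, 0.1, 50)  # 50 kg C m-2
#' @export
core_storage <- function(depth_cm, bulk_density, content_pct) {
  depth_cm * bulk_density * content_pct / 100 * 10
}

#' Sample synthetic peat cores from a landscape
#'
#' Draws cores from cells with peat present (sampling probability
#' proportional to peat area), assigns each a bulk density and organic C /
#' total N content, and computes storages with [core_storage()].
#'
#' @param grid a [landscape_grid] object.
#' @param n number of cores (>= 1).
#' @param seed integer seed (local to this call).
#' @param replace sample cells with replacement? If `FALSE`, `n` may not
#'   exceed the number of peat cells.
#' @param config the [synth_config()] supplying bulk-density and content
#'   distributions.
#' @return a data frame of class `"peat_cores"` with columns `site_id`,
#'   `depth_cm`, `oc_pct`, `bulk_density`, `n_pct`, `c_storage`,
#'   `n_storage`, `maat`, `permafrost` (logical, cell permafrost fraction
#'   above 0.5).
#' @export
sample_peat_cores <- function(grid, n, seed = 1L, replace = TRUE,
                              config = synth_config()) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (!is.numeric(n) || n < 1) stop("'n' must be at least 1")
  peat_cells <- which(grid$peat_fraction > 0)
  if (!length(peat_cells)) stop("grid has no peat cells")
  if (!replace && n > length(peat_cells))
    stop("'n' exceeds the number of peat cells for sampling ",
         "without replacement")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cells <- sample(peat_cells, n, replace = replace,
                  prob = grid$peat_fraction[peat_cells])
  depth <- grid$peat_depth[cells]
  bd <- stats::rlnorm(n, log(config$bd_median), config$bd_sdlog)
  oc <- rtnorm_ab(n, config$oc_mean, config$oc_sd, 10, 60)
  npct <- rtnorm_ab(n, config$n_mean, config$n_sd, 0.2, 5)
  out <- data.frame(
    site_id = sprintf("core_%05d", seq_len(n)),
    depth_cm = depth,
    oc_pct = oc,
    bulk_density = bd,
    n_pct = npct,
    c_storage = core_storage(depth, bd, oc),
    n_storage = core_storage(depth, bd, npct),
    maat = grid$maat[cells],
    permafrost = grid$permafrost_fraction[cells] > 0.5)
  class(out) <- c("peat_cores", "data.frame")
  out
}
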