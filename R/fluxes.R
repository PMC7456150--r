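#' Logistic carbon-accumulation model parameters
#'
#' Long-term apparent C accumulation as an S-shaped (logistic) function of
#' MAAT, saturating at both cold and warm temperatures:
#' `rate = k / (1 + exp(-r * (maat - m)))`, in g C m-2 y-1.
#'
#' Defaults (k = 65, r = 0.25 per degree C, m = -4 degrees C) were chosen
#' once so that the area-weighted mean rate over the default synthetic
#' landscape is close to 34 g C m-2 y-1, the regional mean of the
#' underlying paleo-synthesis, with the midpoint in the boreal MAAT range.
#'
#' @param k asymptotic accumulation, g C m-2 y-1 (> 0).
#' @param r steepness, per degree C (> 0).
#' @param m midpoint MAAT, degrees C.
#' @return an object of class `"accumulation_params"`.
#' @export
accumulation_params <- function(k = 65, r = 0.25, m = -4) {
  if (k <= 0 || r <= 0) stop("'k' and 'r' must be positive")
  structure(list(k = k, r = r, m = m), class = "accumulation_params")
}

#' Long-term C accumulation rate at a given MAAT
#'
#' @param maat mean annual air temperature, degrees C (vectorised).
#' @param params an [accumulation_params()] object.
#' @return accumulation rate, g C m-2 y-1 (non-negative, increasing in
#'   MAAT, `k/2` at the midpoint).
#' @examples
#' accumulation_rate(-4)   # k/2
#' @export
accumulation_rate <- function(maat, params = accumulation_params()) {
  stopifnot(inherits(params, "accumulation_params"))
  params$k / (1 + exp(-params$r * (maat - params$m)))
}

#' Refit the logistic accumulation model from (MAAT, rate) pairs
#'
#' Nonlinear least squares (Levenberg-Marquardt).
#'
#' @param maat,rate observation vectors.
#' @param start starting [accumulation_params()].
#' @return a fitted [accumulation_params()] with attribute `fit` (the
#'   `nls` object).
#' @export
fit_accumulation_model <- function(maat, rate,
                                   start = accumulation_params()) {
  stopifnot(length(maat) == length(rate), length(maat) >= 4)
  df <- data.frame(maat = maat, rate = rate)
  fit <- minpack.lm::nlsLM(rate ~ k / (1 + exp(-r * (maat - m))),
                           data = df,
                           start = list(k = start$k, r = start$r,
                                        m = start$m),
                           lower = c(k = 1e-6, r = 1e-6, m = -50),
                           upper = c(k = 1e3, r = 5, m = 50))
  cf <- stats::coef(fit)
  out <- accumulation_params(k = cf[["k"]], r = cf[["r"]], m = cf[["m"]])
  attr(out, "fit") <- fit
  out
}

#' Default stage-by-type annual flux table
#'
#' Annual per-area fluxes for each thaw/recovery stage and peatland type
#' (minerotrophic fen-like vs ombrotrophic bog-like). Sign convention:
#' positive = emission to the atmosphere (or lateral export), negative =
#' uptake. Units: g C m-2 y-1 for `co2`, `ch4`, `lateral_c`; g N m-2 y-1
#' for `n2o`, `lateral_n`.
#'
#' The source synthesis tables are not printed in the open literature, so
#' these defaults are calibrated reference values: CH4 entries reproduce
#' the regional present-day CH4 source of ~0.026 Pg C y-1 over the default
#' landscape (fen > bog >> intact permafrost, which is near-neutral), and
#' N2O/lateral entries land near the printed regional totals (0.022 Tg N,
#' 0.022 Pg C, 0.7 Tg N per year). The `co2` entries for the young
#' thermokarst and stabilized stages are reference values only: scenario
#' CO2 in those stages comes from the accumulation model (see
#' [run_thaw_scenario()]).
#'
#' @return a data frame of class `"stage_flux_table"` with columns
#'   `stage`, `type`, `co2`, `ch4`, `n2o`, `lateral_c`, `lateral_n`.
#' @export
default_stage_flux_table <- function() {
  tab <- rbind(
    data.frame(stage = "intact_permafrost",      type = c("minerotrophic", "ombrotrophic"),
               co2 = c(-20, -15), ch4 = c(1.0, 0.4), n2o = c(0.004, 0.002),
               lateral_c = c(6, 6), lateral_n = c(0.19, 0.19)),
    data.frame(stage = "active_layer_deepening", type = c("minerotrophic", "ombrotrophic"),
               co2 = c(30, 20), ch4 = c(1.2, 0.5), n2o = c(0.010, 0.006),
               lateral_c = c(6, 6), lateral_n = c(0.19, 0.19)),
    data.frame(stage = "young_thermokarst",      type = c("minerotrophic", "ombrotrophic"),
               co2 = c(-30, -20), ch4 = c(30, 18), n2o = c(0.004, 0.002),
               lateral_c = c(6, 6), lateral_n = c(0.19, 0.19)),
    data.frame(stage = "stabilized",             type = c("minerotrophic", "ombrotrophic"),
               co2 = c(-35, -25), ch4 = c(22, 10), n2o = c(0.006, 0.002),
               lateral_c = c(6, 6), lateral_n = c(0.19, 0.19)),
    data.frame(stage = "nonpermafrost",          type = c("minerotrophic", "ombrotrophic"),
               co2 = c(-35, -25), ch4 = c(19, 6), n2o = c(0.010, 0.003),
               lateral_c = c(6, 6), lateral_n = c(0.19, 0.19)))
  validate_flux_table(tab)
}

#' Validate a stage flux table
#'
#' Checks completeness (all 5 stages x 2 types), finiteness and magnitude
#' (< 1000 in absolute value).
#'
#' @param tab a data frame with the columns of
#'   [default_stage_flux_table()].
#' @return the table, classed `"stage_flux_table"`, invisibly usable.
#' @export
validate_flux_table <- function(tab) {
  stages <- c("intact_permafrost", "active_layer_deepening",
              "young_thermokarst", "stabilized", "nonpermafrost")
  types <- c("minerotrophic", "ombrotrophic")
  need <- c("stage", "type", "co2", "ch4", "n2o", "lateral_c", "lateral_n")
  if (!all(need %in% names(tab)))
    stop("flux table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  key <- paste(tab$stage, tab$type)
  want <- as.vector(outer(stages, types, paste))
  if (!all(want %in% key))
    stop("flux table missing cells: ",
         paste(setdiff(want, key), collapse = "; "))
  vals <- as.matrix(tab[, c("co2", "ch4", "n2o", "lateral_c", "lateral_n")])
  if (any(!is.finite(vals))) stop("flux table contains non-finite values")
  if (any(abs(vals) >= 1e3)) stop("flux magnitudes must be below 1000")
  class(tab) <- c("stage_flux_table", "data.frame")
  tab
}

# Look up one gas column for a stage, returning c(minerotrophic,
# ombrotrophic) in that order.
flux_lookup <- function(tab, stage, gas) {
  rows <- tab[tab$stage == stage, ]
  c(rows[[gas]][rows$type == "minerotrophic"],
    rows[[gas]][rows$type == "ombrotrophic"])
}

#' Default per-biome minerotrophic/ombrotrophic shares
#'
#' Placeholder splits of peatland type within biomes (the source national
#' mapping is not printed): tundra 0.7/0.3, boreal 0.55/0.45, other
#' 0.5/0.5. Config-first: pass your own table to
#' [partition_peatland_types()].
#'
#' @return data frame with columns `biome`, `minerotrophic`,
#'   `ombrotrophic`.
#' @export
default_biome_type_shares <- function() {
  data.frame(biome = c("tundra", "boreal", "other"),
             minerotrophic = c(0.70, 0.55, 0.50),
             ombrotrophic  = c(0.30, 0.45, 0.50))
}

#' Fill peatland type shares per cell from a per-biome table
#'
#' @param grid a [landscape_grid] object with `biome_class` assigned.
#' @param shares a per-biome share table as in
#'   [default_biome_type_shares()]; each row must sum to 1.
#' @return the grid with `minero_frac` and `ombro_frac` filled.
#' @export
partition_peatland_types <- function(grid,
                                     shares = default_biome_type_shares()) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (any(abs(shares$minerotrophic + shares$ombrotrophic - 1) > 1e-8))
    stop("type shares must sum to 1 in every biome row")
  unknown <- setdiff(unique(grid$biome_class), shares$biome)
  if (length(unknown))
    stop("unknown biome class: ", paste(unknown, collapse = ", "))
  idx <- match(grid$biome_class, shares$biome)
  grid$minero_frac <- shares$minerotrophic[idx]
  grid$ombro_frac <- shares$ombrotrophic[idx]
  grid
}

#' Baseline (stable-state) regional C and N flux budget
#'
#' Assembles the present-day regional budget: the CO2 term is the
#' area-weighted long-term net C accumulation (a sink, negative), while
#' CH4, N2O and lateral terms come from the stage flux table weighted by
#' baseline stage occupancy -- intact permafrost versus nonpermafrost, in
#' proportion to each cell's permafrost fraction -- and by the cell's
#' peatland type shares. Areas are weighted by `cell_area *
#' peat_fraction`.
#'
#' @param grid a [landscape_grid] object with type shares filled.
#' @param table a validated stage flux table.
#' @param params [accumulation_params()] for the CO2 term.
#' @return an object of class `"flux_budget"`: list with `co2_pgc`,
#'   `ch4_pgc`, `lateral_c_pgc` (Pg C y-1), `n2o_tgn`, `lateral_n_tgn`
#'   (Tg N y-1). Negative = removal from the atmosphere.
#' @export
baseline_flux_budget <- function(grid, table = default_stage_flux_table(),
                                 params = accumulation_params()) {
  stopifnot(inherits(grid, "landscape_grid"))
  table <- validate_flux_table(table)
  if (any(is.na(grid$minero_frac)))
    stop("type shares missing: run partition_peatland_types() first")
  a_m2 <- grid$cell_area * 1e6 * grid$peat_fraction
  pf <- grid$permafrost_fraction

  type_mix <- function(stage, gas) {
    fx <- flux_lookup(table, stage, gas)
    grid$minero_frac * fx[1] + grid$ombro_frac * fx[2]
  }
  occ_flux <- function(gas)
    sum(a_m2 * (pf * type_mix("intact_permafrost", gas) +
                  (1 - pf) * type_mix("nonpermafrost", gas)))

  co2_g <- -sum(a_m2 * accumulation_rate(grid$maat, params))
  structure(list(
    co2_pgc = co2_g / 1e15,
    ch4_pgc = occ_flux("ch4") / 1e15,
    n2o_tgn = occ_flux("n2o") / 1e12,
    lateral_c_pgc = occ_flux("lateral_c") / 1e15,
    lateral_n_tgn = occ_flux("lateral_n") / 1e12),
    class = "flux_budget")
}

#' @export
print.flux_budget <- function(x, ...) {
  cat("Regional peatland flux budget (negative = uptake):\n")
  cat(sprintf("  CO2       %+.4f Pg C/y\n", x$co2_pgc))
  cat(sprintf("  CH4       %+.4f Pg C/y\n", x$ch4_pgc))
  cat(sprintf("  N2O       %+.4f Tg N/y\n", x$n2o_tgn))
  cat(sprintf("  lateral C %+.4f Pg C/y\n", x$lateral_c_pgc))
  cat(sprintf("  lateral N %+.4f Tg N/y\n", x$lateral_n_tgn))
  invisible(x)
}
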