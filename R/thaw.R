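#' Thaw-stage transition timings
#'
#' Durations of the transient thaw stages. Active-layer deepening lasts
#' 25-75 y (mean 50), set by a deepening rate of ~1 cm/y over the 25-75 cm
#' that typically separate the active-layer base from ice-rich peat.
#' Young thermokarst systems mature over 50-150 y (mean 100).
#'
#' @param ald_duration mean active-layer-deepening duration, y.
#' @param ald_range min/max of the same, y.
#' @param tk_duration mean young-thermokarst maturation time, y.
#' @param tk_range min/max of the same, y.
#' @param ald_rate active-layer deepening rate, cm/y.
#' @param depth_to_ice min/max depth from active-layer base to ice-rich
#'   peat, cm.
#' @return an object of class `"thaw_timings"`.
#' @export
thaw_timings <- function(ald_duration = 50, ald_range = c(25, 75),
                         tk_duration = 100, tk_range = c(50, 150),
                         ald_rate = 1, depth_to_ice = c(25, 75)) {
  chk <- function(mean, range, what) {
    if (any(range <= 0) || mean < range[1] || mean > range[2])
      stop("'", what, "' mean must lie inside its positive range")
  }
  chk(ald_duration, ald_range, "ald_duration")
  chk(tk_duration, tk_range, "tk_duration")
  structure(list(ald_duration = ald_duration, ald_range = ald_range,
                 tk_duration = tk_duration, tk_range = tk_range,
                 ald_rate = ald_rate, depth_to_ice = depth_to_ice),
            class = "thaw_timings")
}

#' Chronosequence carbon-loss model
#'
#' The fraction of prethaw C lost in the first 100 y after thaw, as a
#' function of the prethaw stock x (kg C m-2):
#' `y = min(1, a * x^b)` with a = 1.1451, b = -0.0771. Because the raw
#' power law gives ~0.8 loss fractions at typical stocks -- far above
#' observed landscape-mean losses -- only `eligible_fraction` of the
#' prethaw stock is treated as subject to chronosequence loss (default
#' 0.18, reconciling the curve with landscape-average losses of 11-18
#' kg C m-2 per thawed unit). Loss is released uniformly over `horizon`
#' years.
#'
#' @param a,b power-law coefficient and exponent.
#' @param horizon release horizon, y.
#' @param eligible_fraction fraction of the prethaw stock subject to loss,
#'   in (0, 1].
#' @return an object of class `"loss_model"`.
#' @export
loss_model <- function(a = 1.1451, b = -0.0771, horizon = 100,
                       eligible_fraction = 0.18) {
  if (eligible_fraction <= 0 || eligible_fraction > 1)
    stop("'eligible_fraction' must lie in (0, 1]")
  if (horizon <= 0) stop("'horizon' must be positive")
  structure(list(a = a, b = b, horizon = horizon,
                 eligible_fraction = eligible_fraction),
            class = "loss_model")
}

#' Fraction of prethaw C lost within 100 y of thaw
#'
#' Evaluates the clamped power law of [loss_model()] at the full prethaw
#' stock (eligibility scaling is applied downstream, when the fraction is
#' turned into a mass loss).
#'
#' @param stock prethaw C stock, kg C m-2 (vectorised, > 0).
#' @param model a [loss_model()] object.
#' @return loss fraction in `[0, 1]`; equals 1 for stocks at or below
#'   `a^(-1/b)` (about 5.8 kg C m-2 with defaults).
#' @examples
#' loss_fraction_100y(100)  # ~0.803
#' @export
loss_fraction_100y <- function(stock, model = loss_model()) {
  if (any(stock <= 0)) stop("prethaw stock must be positive")
  pmin(1, model$a * stock^model$b)
}

# Triangular(min, mode, max) sampler by inverse CDF.
rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

# Length of overlap of [t, t+1) with [from, to).
year_overlap <- function(t, from, to) {
  pmax(0, pmin(t + 1, to) - pmax(t, from))
}

#' Stage occupancy schedule for a thawed peatland unit
#'
#' Once the thaw threshold is crossed (at `onset`), a fraction
#' `tk_fraction` of the thawed area follows the thermokarst pathway:
#' active-layer deepening (duration d1), young thermokarst (d2), then
#' stabilized. The remainder follows an extended active-layer-deepening
#' pathway (duration 2 d1) directly into the stabilized stage. In
#' deterministic mode d1, d2 are the timing means (stage boundaries at
#' onset+50 and onset+150 y for the thermokarst path); in sampled mode
#' they are drawn from triangular distributions over the stated ranges.
#' Occupancies are exact fractional overlaps of stage intervals with
#' annual steps and sum to 1 at every step.
#'
#' @param onset thaw onset year (>= 0).
#' @param timings a [thaw_timings()] object.
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed seed for sampled mode (local to this call).
#' @param horizon schedule length, y.
#' @param tk_fraction fraction of thawed area on the thermokarst pathway.
#' @return data frame with `year` (step start, 0-based) and occupancy
#'   columns `intact`, `active_layer_deepening`, `young_thermokarst`,
#'   `stabilized`, each row summing to 1.
#' @export
stage_schedule <- function(onset = 0, timings = thaw_timings(),
                           mode = c("deterministic", "sampled"),
                           seed = 1L, horizon = 400, tk_fraction = 0.5) {
  mode <- match.arg(mode)
  if (onset < 0) stop("'onset' must be non-negative")
  if (tk_fraction < 0 || tk_fraction > 1)
    stop("'tk_fraction' must lie in [0, 1]")
  if (mode == "sampled") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    d1 <- rtriangular(1, timings$ald_range[1], timings$ald_duration,
                      timings$ald_range[2])
    d2 <- rtriangular(1, timings$tk_range[1], timings$tk_duration,
                      timings$tk_range[2])
  } else {
    d1 <- timings$ald_duration
    d2 <- timings$tk_duration
  }
  t <- 0:(horizon - 1)
  # thermokarst pathway
  tk <- cbind(intact = year_overlap(t, -Inf, onset),
              ald    = year_overlap(t, onset, onset + d1),
              tkst   = year_overlap(t, onset + d1, onset + d1 + d2),
              stab   = year_overlap(t, onset + d1 + d2, Inf))
  # extended active-layer-deepening pathway
  ex <- cbind(intact = year_overlap(t, -Inf, onset),
              ald    = year_overlap(t, onset, onset + 2 * d1),
              tkst   = 0,
              stab   = year_overlap(t, onset + 2 * d1, Inf))
  occ <- tk_fraction * tk + (1 - tk_fraction) * ex
  out <- data.frame(year = t,
                    intact = occ[, "intact"],
                    active_layer_deepening = occ[, "ald"],
                    young_thermokarst = occ[, "tkst"],
                    stabilized = occ[, "stab"])
  attr(out, "durations") <- c(ald = d1, thermokarst = d2)
  out
}

#' Default C:N ratio table
#'
#' Typical C:N mass ratios of peat by permafrost status (class-mean C and
#' N storages: 108/4.2 for permafrost, 123/1.9 for permafrost-free peat).
#' The same default is used across biomes; supply a custom table for
#' biome-specific ratios.
#'
#' @return data frame with columns `status`, `tundra`, `boreal`, `other`.
#' @export
cn_ratio_table <- function() {
  data.frame(status = c("permafrost", "nonpermafrost"),
             tundra = c(108 / 4.2, 123 / 1.9),
             boreal = c(108 / 4.2, 123 / 1.9),
             other  = c(108 / 4.2, 123 / 1.9))
}

#' Scale N losses from C losses via C:N ratios
#'
#' @param c_loss C loss mass (any unit; >= 0, vectorised).
#' @param table a C:N table as in [cn_ratio_table()].
#' @param status `"permafrost"` or `"nonpermafrost"`.
#' @param biome `"tundra"`, `"boreal"` or `"other"` (vectorised).
#' @return N loss in the same mass unit.
#' @examples
#' scale_n_losses(25.7, status = "permafrost")  # ~1
#' @export
scale_n_losses <- function(c_loss, table = cn_ratio_table(),
                           status = "permafrost", biome = "boreal") {
  if (any(c_loss < 0)) stop("'c_loss' must be non-negative")
  if (!status %in% table$status) stop("unknown status: ", status)
  if (!all(biome %in% c("tundra", "boreal", "other")))
    stop("unknown biome class")
  ratios <- unlist(table[table$status == status, c("tundra", "boreal",
                                                   "other")])
  unname(c_loss / ratios[biome])
}

#' Scenario configuration for thaw projections
#'
#' @param timings [thaw_timings()].
#' @param loss [loss_model()].
#' @param flux_table stage flux table ([default_stage_flux_table()]).
#' @param acc_params [accumulation_params()].
#' @param cn_table C:N table ([cn_ratio_table()]).
#' @param curve_params [permafrost_params()] used for thaw extents.
#' @param amplification regional/global warming ratio.
#' @param tk_fraction thermokarst-pathway share of thawed area.
#' @param horizon scenario length, y.
#' @param mode,seed stage-duration mode and seed (see [stage_schedule()]).
#' @param n2o_c_ratio g N2O-N released per g CO2-C released during
#'   active-layer deepening (mesocosm-derived scaling; default small so
#'   scenario N2O forcing stays minimal).
#' @param co2_route_fraction fraction of chronosequence old-C loss routed
#'   to CO2 instead of the lateral pathway (default 0: all lateral).
#' @return an object of class `"thaw_config"`.
#' @export
thaw_config <- function(timings = thaw_timings(), loss = loss_model(),
                        flux_table = default_stage_flux_table(),
                        acc_params = accumulation_params(),
                        cn_table = cn_ratio_table(),
                        curve_params = permafrost_params("central"),
                        amplification = 2, tk_fraction = 0.5,
                        horizon = 400,
                        mode = c("deterministic", "sampled"), seed = 1L,
                        n2o_c_ratio = 0.001, co2_route_fraction = 0) {
  mode <- match.arg(mode)
  flux_table <- validate_flux_table(flux_table)
  if (co2_route_fraction < 0 || co2_route_fraction > 1)
    stop("'co2_route_fraction' must lie in [0, 1]")
  structure(list(timings = timings, loss = loss, flux_table = flux_table,
                 acc_params = acc_params, cn_table = cn_table,
                 curve_params = curve_params,
                 amplification = amplification,
                 tk_fraction = tk_fraction, horizon = horizon,
                 mode = mode, seed = seed, n2o_c_ratio = n2o_c_ratio,
                 co2_route_fraction = co2_route_fraction),
            class = "thaw_config")
}

#' Run a permafrost-thaw scenario on a landscape
#'
#' Projects the C and N consequences of stabilised global warming. Per
#' cell, the thawed permafrost area is
#' `peat_fraction * (f(maat) - f(maat + amplification * (warming - 0.5)))`
#' from the equilibrium curve (warm cap applied). The thawed area moves
#' through the stage schedule; stage GHG fluxes come from the flux table
#' (weighted by peatland-type shares), new-C gains in the thermokarst and
#' stabilized stages come from the accumulation model at the shifted MAAT,
#' chronosequence old-C losses are released uniformly over the loss-model
#' horizon (routed laterally by default), and N losses are scaled from C
#' losses with the C:N table. All reported flux series are net changes
#' relative to the intact-permafrost baseline of the same area.
#'
#' @param grid a [landscape_grid] object with type shares filled.
#' @param warming global warming stabilization level, degrees C in
#'   `[0.5, 6]`.
#' @param config a [thaw_config()] object.
#' @return an object of class `"thaw_scenario"`: list with `warming`,
#'   `series` (annual data frame: year; stage areas in km2; net `co2_pgc`,
#'   `ch4_pgc`, `lateral_c_pgc` in Pg C/y; net `n2o_tgn`, `lateral_n_tgn`
#'   in Tg N/y; raw old-C loss series `old_gaseous_pgc`, `old_lateral_pgc`;
#'   pools `old_c_pg`, `new_c_pg`), and `totals` (thawed area, initial old
#'   C, cumulative losses, lateral loss per thawed m2).
#' @export
run_thaw_scenario <- function(grid, warming, config = thaw_config()) {
  stopifnot(inherits(grid, "landscape_grid"),
            inherits(config, "thaw_config"))
  if (warming < 0.5 || warming > 6)
    stop("'warming' must lie in [0.5, 6] degrees C")
  if (any(is.na(grid$minero_frac)))
    stop("type shares missing: run partition_peatland_types() first")

  shift <- config$amplification * (warming - 0.5)
  f0 <- permafrost_fraction(grid$maat, config$curve_params,
                            apply_cap = TRUE)
  f1 <- permafrost_fraction(grid$maat + shift, config$curve_params,
                            apply_cap = TRUE)
  thaw_a <- grid$cell_area * 1e6 * grid$peat_fraction * pmax(0, f0 - f1)
  A <- sum(thaw_a)                                   # m2 thawed

  tab <- config$flux_table
  type_mix <- function(stage, gas) {
    fx <- flux_lookup(tab, stage, gas)
    grid$minero_frac * fx[1] + grid$ombro_frac * fx[2]
  }
  # area-integrated stage fluxes over the thawed area, g per year at full
  # occupancy
  stages <- c("intact_permafrost", "active_layer_deepening",
              "young_thermokarst", "stabilized")
  Fs <- lapply(c(ch4 = "ch4", n2o = "n2o", lateral_c = "lateral_c",
                 lateral_n = "lateral_n"), function(gas)
    vapply(stages, function(s) sum(thaw_a * type_mix(s, gas)), numeric(1)))
  co2_ald <- sum(thaw_a * type_mix("active_layer_deepening", "co2"))
  acc_base <- sum(thaw_a * accumulation_rate(grid$maat, config$acc_params))
  acc_new  <- sum(thaw_a * accumulation_rate(grid$maat + shift,
                                             config$acc_params))

  # chronosequence old-C loss (g over the loss horizon)
  has <- thaw_a > 0 & grid$c_storage > 0
  L_cell <- numeric(length(thaw_a))
  L_cell[has] <- thaw_a[has] * config$loss$eligible_fraction *
    grid$c_storage[has] *
    loss_fraction_100y(grid$c_storage[has], config$loss) * 1000  # kg->g
  L_total <- sum(L_cell)
  ratios <- scale_n_losses(1, config$cn_table, "permafrost",
                           grid$biome_class)
  LN_total <- sum(L_cell * ratios)                  # g N

  occ <- stage_schedule(0, config$timings, config$mode, config$seed,
                        config$horizon, config$tk_fraction)
  o_ald <- occ$active_layer_deepening
  o_tk <- occ$young_thermokarst
  o_st <- occ$stabilized
  t <- occ$year
  in_h <- as.numeric(t < config$loss$horizon)
  L_ann  <- L_total / config$loss$horizon * in_h    # g C / y
  LN_ann <- LN_total / config$loss$horizon * in_h

  route <- config$co2_route_fraction
  # scenario gross fluxes (g/y), positive = emission
  co2_scen <- o_ald * co2_ald - (o_tk + o_st) * acc_new + route * L_ann
  ch4_scen <- o_ald * Fs$ch4["active_layer_deepening"] +
    o_tk * Fs$ch4["young_thermokarst"] + o_st * Fs$ch4["stabilized"]
  n2o_scen <- o_ald * (Fs$n2o["active_layer_deepening"] +
                         config$n2o_c_ratio * max(co2_ald, 0)) +
    o_tk * Fs$n2o["young_thermokarst"] + o_st * Fs$n2o["stabilized"]
  lat_c_scen <- o_ald * Fs$lateral_c["active_layer_deepening"] +
    o_tk * Fs$lateral_c["young_thermokarst"] +
    o_st * Fs$lateral_c["stabilized"] + (1 - route) * L_ann
  lat_n_scen <- o_ald * Fs$lateral_n["active_layer_deepening"] +
    o_tk * Fs$lateral_n["young_thermokarst"] +
    o_st * Fs$lateral_n["stabilized"] + LN_ann

  # intact-permafrost baseline of the same (pre-thaw) area
  base_co2 <- -acc_base
  base <- vapply(Fs, `[[`, numeric(1), "intact_permafrost")

  # old-C pool bookkeeping (g)
  old_gas <- o_ald * pmax(co2_ald, 0)
  old_lat <- L_ann
  initial_old <- sum(thaw_a * grid$c_storage) * 1000
  old_pool <- initial_old - cumsum(old_gas) - cumsum(old_lat)
  new_pool <- cumsum((o_tk + o_st) * acc_new)

  a_peat_km2 <- sum(grid$cell_area * grid$peat_fraction)
  series <- data.frame(
    year = t,
    area_intact_km2 = a_peat_km2 - A / 1e6 + occ$intact * A / 1e6,
    area_ald_km2 = o_ald * A / 1e6,
    area_thermokarst_km2 = o_tk * A / 1e6,
    area_stabilized_km2 = o_st * A / 1e6,
    co2_pgc = (co2_scen - base_co2) / 1e15,
    ch4_pgc = (ch4_scen - base["ch4"]) / 1e15,
    n2o_tgn = (n2o_scen - base["n2o"]) / 1e12,
    lateral_c_pgc = (lat_c_scen - base["lateral_c"]) / 1e15,
    lateral_n_tgn = (lat_n_scen - base["lateral_n"]) / 1e12,
    old_gaseous_pgc = old_gas / 1e15,
    old_lateral_pgc = old_lat / 1e15,
    old_c_pg = old_pool / 1e15,
    new_c_pg = new_pool / 1e15)

  totals <- list(
    thawed_area_mkm2 = A / 1e12,
    initial_old_c_pg = initial_old / 1e15,
    cum_lateral_old_pg = sum(old_lat) / 1e15,
    cum_gaseous_old_pg = sum(old_gas) / 1e15,
    cum_net_co2_pg = sum(series$co2_pgc),
    cum_net_ch4_pg = sum(series$ch4_pgc),
    cum_net_n2o_tg = sum(series$n2o_tgn),
    cum_lateral_n_tg = sum(LN_ann) / 1e12,
    lateral_per_thawed_m2_kg = if (A > 0) L_total / 1000 / A else NA_real_)

  structure(list(warming = warming, series = series, totals = totals,
                 config = config),
            class = "thaw_scenario")
}

#' @export
print.thaw_scenario <- function(x, ...) {
  cat(sprintf("Permafrost thaw scenario at +%.1f C warming\n", x$warming))
  cat(sprintf("  thawed peatland area: %.3f Mkm2\n",
              x$totals$thawed_area_mkm2))
  cat(sprintf("  cumulative lateral old-C loss: %.2f Pg C (%.1f kg C/m2 thawed)\n",
              x$totals$cum_lateral_old_pg,
              x$totals$lateral_per_thawed_m2_kg))
  cat(sprintf("  cumulative net CO2 %.2f, CH4 %.2f Pg C over %d y\n",
              x$totals$cum_net_co2_pg, x$totals$cum_net_ch4_pg,
              x$config$horizon))
  invisible(x)
}
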