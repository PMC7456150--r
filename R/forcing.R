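#' Radiative forcing constants
#'
#' Impulse-response and conversion constants for the forcing engine,
#' defaulting to the IPCC AR5 parameterization: the four-term CO2
#' impulse-response function (a permanent airborne fraction 0.2173 plus
#' decaying fractions with time constants 394.4, 36.54 and 4.304 y),
#' single-lifetime decay for CH4 (12.4 y) and N2O (121 y), per-ppb
#' radiative efficiencies, a CH4 indirect-effect multiplier of 1.65
#' (tropospheric ozone and stratospheric water vapour), and mass-to-mixing
#' ratio factors (2.124 Pg C per ppm CO2; 2.75 Tg CH4 per ppb; 4.81 Tg N2O
#' per ppb).
#'
#' @param co2_amps amplitudes of the CO2 impulse-response terms (sum to 1);
#'   the first term is permanent.
#' @param co2_taus time constants of the decaying terms, y (first is
#'   `Inf`).
#' @param ch4_tau,n2o_tau atmospheric lifetimes, y.
#' @param eff_co2,eff_ch4,eff_n2o radiative efficiencies, W m-2 ppb-1.
#' @param ch4_indirect CH4 indirect-effect multiplier.
#' @param pgc_per_ppm_co2 Pg C per ppm CO2.
#' @param tg_per_ppb_ch4 Tg CH4 per ppb.
#' @param tg_per_ppb_n2o Tg N2O per ppb.
#' @return an object of class `"forcing_constants"`.
#' @export
forcing_constants <- function(co2_amps = c(0.2173, 0.2240, 0.2824, 0.2763),
                              co2_taus = c(Inf, 394.4, 36.54, 4.304),
                              ch4_tau = 12.4, n2o_tau = 121,
                              eff_co2 = 1.37e-5, eff_ch4 = 3.63e-4,
                              eff_n2o = 3.00e-3, ch4_indirect = 1.65,
                              pgc_per_ppm_co2 = 2.124,
                              tg_per_ppb_ch4 = 2.75,
                              tg_per_ppb_n2o = 4.81) {
  if (abs(sum(co2_amps) - 1) > 1e-6)
    stop("CO2 impulse-response amplitudes must sum to 1")
  if (length(co2_amps) != length(co2_taus))
    stop("amplitude/time-constant length mismatch")
  if (ch4_tau <= 0 || n2o_tau <= 0 || any(co2_taus <= 0))
    stop("lifetimes must be positive")
  if (eff_co2 <= 0 || eff_ch4 <= 0 || eff_n2o <= 0)
    stop("radiative efficiencies must be positive")
  structure(as.list(environment()), class = "forcing_constants")
}

#' Construct a greenhouse-gas flux series
#'
#' Fluxes are annual-mean rates on a uniform time grid; emissions are
#' taken as uniform over each step. CO2 and CH4 fluxes are in Pg C per
#' year (CH4 as carbon), N2O in Tg N per year; negative = uptake.
#'
#' @param time uniform time grid, years.
#' @param co2_pgc,ch4_pgc,n2o_tgn flux vectors (recycled if scalar).
#' @return an object of class `"flux_series"` (a data frame).
#' @export
flux_series <- function(time, co2_pgc = 0, ch4_pgc = 0, n2o_tgn = 0) {
  if (length(time) < 2) stop("time grid needs at least 2 points")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt))))
    stop("time grid must be uniform")
  out <- data.frame(time = time,
                    co2_pgc = rep_len(co2_pgc, length(time)),
                    ch4_pgc = rep_len(ch4_pgc, length(time)),
                    n2o_tgn = rep_len(n2o_tgn, length(time)))
  if (any(!is.finite(as.matrix(out)))) stop("fluxes must be finite")
  class(out) <- c("flux_series", "data.frame")
  out
}

#' Convert a thaw scenario into a flux series
#'
#' Maps the net annual flux changes of a [run_thaw_scenario()] result onto
#' the flux-series container of the forcing engine (CH4 carried as C).
#'
#' @param scenario a `thaw_scenario` object.
#' @return a [flux_series()].
#' @export
scenario_flux_series <- function(scenario) {
  stopifnot(inherits(scenario, "thaw_scenario"))
  s <- scenario$series
  flux_series(s$year, co2_pgc = s$co2_pgc, ch4_pgc = s$ch4_pgc,
              n2o_tgn = s$n2o_tgn)
}

# Midpoint-lag convolution of per-step emitted masses with a decay
# kernel: emissions are uniform over each step, burdens are reported at
# step edges, so the kernel is evaluated at lags (i - j - 0.5) * dt.
# pert[1] (time of the first grid point) is zero by construction.
conv_burden <- function(mass, kern, dt) {
  n <- length(mass)
  pert <- numeric(n)
  for (i in 2:n) {
    lags <- (i - 1:(i - 1) - 0.5) * dt
    pert[i] <- sum(mass[1:(i - 1)] * kern(lags))
  }
  pert
}

#' Atmospheric burden perturbations from a flux series
#'
#' CH4 and N2O burdens follow single-exponential decay with the gas
#' lifetime; CO2 follows the multi-term impulse-response function. Fluxes
#' enter as element masses (C for CO2 and CH4, N for N2O), are converted
#' to full-molecule mass (x44/12, x16/12, x44/28) and then to mixing
#' ratios. Emissions are uniform over each step and burdens are reported
#' at step edges (midpoint-lag kernel), so the burden at the first time
#' point is zero and a sustained single-lifetime flux F approaches the
#' analytic steady state F*tau.
#'
#' @param flux a [flux_series()].
#' @param constants a [forcing_constants()] object.
#' @return data frame `time`, `co2_ppm`, `ch4_ppb`, `n2o_ppb`.
#' @export
burden_perturbation <- function(flux, constants = forcing_constants()) {
  stopifnot(inherits(flux, "flux_series"),
            inherits(constants, "forcing_constants"))
  dt <- flux$time[2] - flux$time[1]
  co2_irf <- function(l) {
    out <- rep(constants$co2_amps[1], length(l))
    for (k in seq_along(constants$co2_taus)[-1])
      out <- out + constants$co2_amps[k] * exp(-l / constants$co2_taus[k])
    out
  }
  # per-step emitted masses in mixing-ratio units
  m_co2 <- flux$co2_pgc * dt / constants$pgc_per_ppm_co2          # ppm
  m_ch4 <- flux$ch4_pgc * 1e3 * (16 / 12) * dt / constants$tg_per_ppb_ch4
  m_n2o <- flux$n2o_tgn * (44 / 28) * dt / constants$tg_per_ppb_n2o
  data.frame(
    time = flux$time,
    co2_ppm = conv_burden(m_co2, co2_irf, dt),
    ch4_ppb = conv_burden(m_ch4, function(l) exp(-l / constants$ch4_tau),
                          dt),
    n2o_ppb = conv_burden(m_n2o, function(l) exp(-l / constants$n2o_tau),
                          dt))
}

#' Radiative forcing trajectory from a flux series
#'
#' `rf_gas(t) = efficiency * burden(t)`, with the CH4 term scaled by the
#' indirect-effect multiplier; the net forcing is the sum over gases and
#' is linear in the flux magnitudes.
#'
#' @param flux a [flux_series()].
#' @param constants a [forcing_constants()] object.
#' @return an object of class `"forcing_series"`: data frame `time`,
#'   `rf_co2`, `rf_ch4`, `rf_n2o`, `rf_net` (W m-2).
#' @export
forcing_from_flux <- function(flux, constants = forcing_constants()) {
  b <- burden_perturbation(flux, constants)
  out <- data.frame(
    time = b$time,
    rf_co2 = constants$eff_co2 * 1e3 * b$co2_ppm,   # ppm -> ppb
    rf_ch4 = constants$eff_ch4 * constants$ch4_indirect * b$ch4_ppb,
    rf_n2o = constants$eff_n2o * b$n2o_ppb)
  out$rf_net <- out$rf_co2 + out$rf_ch4 + out$rf_n2o
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' Peak and zero-crossing diagnostics of a net forcing series
#'
#' Finds the global maximum of the net forcing and the first sign change
#' after the peak (linearly interpolated). An absent crossing is reported
#' as `crossed = FALSE` with `crossover_time = NA`.
#'
#' @param forcing a [forcing_from_flux()] result (or any data frame with
#'   `time` and `rf_net`).
#' @return list with `peak_wm2`, `peak_time`, `crossover_time`, `crossed`.
#' @export
peak_and_crossover <- function(forcing) {
  if (nrow(forcing) < 2) stop("series needs at least 2 points")
  net <- forcing$rf_net
  i <- which.max(net)
  res <- list(peak_wm2 = net[i], peak_time = forcing$time[i],
              crossover_time = NA_real_, crossed = FALSE)
  if (i < length(net) && net[i] > 0) {
    after <- which(net[(i + 1):length(net)] < 0)
    if (length(after)) {
      j <- i + after[1]                 # first negative point after peak
      t0 <- forcing$time[j - 1]; t1 <- forcing$time[j]
      res$crossover_time <- t0 + net[j - 1] / (net[j - 1] - net[j]) *
        (t1 - t0)
      res$crossed <- TRUE
    }
  }
  res
}

#' Peatland forcing as a percentage of anthropogenic forcing
#'
#' Linearly interpolates the anthropogenic trajectory onto the overlap of
#' the two time grids and reports `100 * peatland / anthropogenic` per
#' year. Years where the anthropogenic forcing is not positive are flagged
#' and reported as `NA`.
#'
#' @param forcing a peatland [forcing_from_flux()] result.
#' @param anthropogenic data frame with `time` and `rf_wm2` (an external
#'   input series; never computed internally).
#' @return data frame `time`, `ratio_pct` with attribute `flagged` (times
#'   with non-positive anthropogenic forcing).
#' @export
compare_to_anthropogenic <- function(forcing, anthropogenic) {
  stopifnot(all(c("time", "rf_wm2") %in% names(anthropogenic)))
  lo <- max(min(forcing$time), min(anthropogenic$time))
  hi <- min(max(forcing$time), max(anthropogenic$time))
  if (lo > hi) stop("time grids do not overlap")
  keep <- forcing$time >= lo & forcing$time <= hi
  tt <- forcing$time[keep]
  a <- stats::approx(anthropogenic$time, anthropogenic$rf_wm2,
                     xout = tt)$y
  bad <- a <= 0
  ratio <- ifelse(bad, NA_real_, 100 * forcing$rf_net[keep] / a)
  if (any(bad))
    warning("anthropogenic forcing non-positive at ", sum(bad),
            " time points: ratio undefined there")
  out <- data.frame(time = tt, ratio_pct = ratio)
  attr(out, "flagged") <- tt[bad]
  out
}
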