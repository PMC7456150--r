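#' Equilibrium permafrost-fraction curve parameters
#'
#' Parameter triplet (mu, sigma, f_max) of the equilibrium relationship
#' between mean annual air temperature (MAAT) and the fraction of peatland
#' area underlain by permafrost,
#' \deqn{f(T) = 0.5\, f_{max}\, \mathrm{erfc}\!\left(\frac{T + \mu}{\sqrt{2}\,\sigma}\right).}
#' Three fitted envelopes are shipped: a central estimate and upper/lower
#' envelopes refitted to maximum/minimum mapped permafrost fractions.
#'
#' @param envelope one of `"central"`, `"upper"`, `"lower"`, selecting a
#'   shipped triplet, ignored when `mu`, `sigma` and `f_max` are all given.
#' @param mu curve midpoint offset, degrees C. The fraction equals
#'   `f_max / 2` at MAAT = `-mu`.
#' @param sigma curve width, degrees C; must be positive.
#' @param f_max asymptotic cold-limit fraction, in (0, 1].
#' @return an object of class `"permafrost_params"`.
#' @examples
#' permafrost_params()                      # central estimate
#' permafrost_params("lower")
#' permafrost_params(mu = 2, sigma = 7, f_max = 0.9)
#' @export
permafrost_params <- function(envelope = c("central", "upper", "lower"),
                              mu = NULL, sigma = NULL, f_max = NULL) {
  envelope <- match.arg(envelope)
  shipped <- list(
    central = list(mu = 1.95, sigma = 7.35, f_max = 0.92),
    upper   = list(mu = 0.70, sigma = 6.10, f_max = 0.96),
    lower   = list(mu = 3.10, sigma = 4.50, f_max = 0.86)
  )
  p <- shipped[[envelope]]
  if (!is.null(mu))    p$mu    <- mu
  if (!is.null(sigma)) p$sigma <- sigma
  if (!is.null(f_max)) p$f_max <- f_max
  stopifnot(is.numeric(p$mu), length(p$mu) == 1, is.finite(p$mu))
  if (!is.numeric(p$sigma) || p$sigma <= 0)
    stop("'sigma' must be positive")
  if (!is.numeric(p$f_max) || p$f_max <= 0 || p$f_max > 1)
    stop("'f_max' must lie in (0, 1]")
  structure(list(mu = p$mu, sigma = p$sigma, f_max = p$f_max,
                 envelope = envelope),
            class = "permafrost_params")
}

#' @export
print.permafrost_params <- function(x, ...) {
  cat(sprintf(
    "Permafrost fraction curve (%s): mu = %.3g, sigma = %.3g, f_max = %.3g\n",
    x$envelope, x$mu, x$sigma, x$f_max))
  invisible(x)
}

#' Equilibrium permafrost fraction at a given MAAT
#'
#' Evaluates the complementary-error-function curve of permafrost fraction
#' versus mean annual air temperature. Under the default convention the
#' argument is scaled by `sqrt(2) * sigma`, the standard erfc form of a
#' normal CDF; `convention = "literal"` divides by `2 * sigma^2` instead,
#' kept only for sensitivity checks (it yields a near-flat curve).
#'
#' @param maat mean annual air temperature, degrees C (vectorised).
#' @param params a [permafrost_params()] object.
#' @param apply_cap if `TRUE`, the fraction is forced to zero where MAAT
#'   exceeds `cap_maat`, mirroring the warm threshold used in map
#'   construction (no permafrost above about +1 degree C).
#' @param cap_maat warm cutoff for the cap, degrees C.
#' @param convention `"sqrt2"` (default) or `"literal"`; see Details.
#' @return numeric vector of fractions in `[0, f_max]`.
#' @examples
#' permafrost_fraction(-1.95)            # f_max / 2 = 0.46
#' permafrost_fraction(5, apply_cap = TRUE)  # 0: above the warm cutoff
#' @export
permafrost_fraction <- function(maat, params = permafrost_params(),
                                apply_cap = FALSE, cap_maat = 1,
                                convention = c("sqrt2", "literal")) {
  convention <- match.arg(convention)
  if (!is.numeric(maat) || any(!is.finite(maat)))
    stop("'maat' must be finite numeric")
  stopifnot(inherits(params, "permafrost_params"))
  denom <- if (convention == "sqrt2") sqrt(2) * params$sigma else
    2 * params$sigma^2
  f <- 0.5 * params$f_max * pracma::erfc((maat + params$mu) / denom)
  if (apply_cap) f[maat > cap_maat] <- 0
  f
}

#' Fit the permafrost-fraction curve to (MAAT, fraction) pairs
#'
#' Estimates (mu, sigma, f_max) by minimising the RMSE between observed and
#' predicted fractions, using a bounded multi-start Nelder-Mead/L-BFGS-B
#' search. Bounds: mu in \[-10, 10\], sigma in (0, 20\], f_max in (0, 1\].
#' Ties between starts are broken by lowest RMSE, then smallest sigma.
#'
#' @param maat numeric vector of MAAT values, degrees C.
#' @param fraction observed permafrost fractions in `[0, 1]`, same length.
#' @param envelope label attached to the fitted parameters.
#' @param binned if `TRUE`, pairs are averaged in `bin_width`-degree MAAT
#'   bins before fitting (per-pixel fitting is the default).
#' @param bin_width bin width in degrees C when `binned = TRUE`.
#' @param n_starts number of multi-start points.
#' @param seed seed for start-point jitter (local to this call).
#' @return a [permafrost_params()] object with attributes `rmse` (achieved
#'   RMSE) and `convergence` (0 = converged).
#' @export
fit_permafrost_curve <- function(maat, fraction,
                                 envelope = c("central", "upper", "lower"),
                                 binned = FALSE, bin_width = 1,
                                 n_starts = 12, seed = 1) {
  envelope <- match.arg(envelope)
  stopifnot(length(maat) == length(fraction))
  ok <- is.finite(maat) & is.finite(fraction)
  maat <- maat[ok]; fraction <- fraction[ok]
  if (length(maat) < 10)
    stop("need at least 10 (maat, fraction) pairs")
  if (diff(range(maat)) < 10)
    stop("pairs must span at least 10 degrees C of MAAT")
  if (stats::sd(fraction) == 0)
    stop("degenerate input: all fractions are equal")

  if (binned) {
    b <- round(maat / bin_width)
    maat <- tapply(maat, b, mean)
    fraction <- tapply(fraction, b, mean)
  }

  rmse_of <- function(par) {
    p <- structure(list(mu = par[1], sigma = par[2], f_max = par[3],
                        envelope = envelope), class = "permafrost_params")
    sqrt(mean((permafrost_fraction(maat, p) - fraction)^2))
  }
  lower <- c(-10, 1e-3, 1e-3); upper <- c(10, 20, 1)

  # moment-based start: midpoint where fraction crosses half its maximum
  fm0 <- min(1, max(fraction))
  mu0 <- -stats::approx(fraction + seq_along(fraction) * 1e-12,
                        maat, xout = fm0 / 2, rule = 2)$y
  starts <- rbind(
    c(mu0, 7, fm0),
    c(permafrost_params(envelope)$mu, permafrost_params(envelope)$sigma,
      permafrost_params(envelope)$f_max))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  while (nrow(starts) < n_starts)
    starts <- rbind(starts, c(stats::runif(1, -8, 8),
                              stats::runif(1, 2, 15),
                              stats::runif(1, 0.5, 1)))
  fits <- apply(starts, 1, function(s) {
    f <- try(stats::optim(pmin(pmax(s, lower), upper), rmse_of,
                          method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = 1e4)),
             silent = TRUE)
    if (inherits(f, "try-error")) NULL else f
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimizer failed to converge from any start")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  sig  <- vapply(fits, function(f) f$par[2], numeric(1))
  conv <- vapply(fits, `[[`, numeric(1), "convergence")
  # ties broken by lowest RMSE, then convergence flag, then smallest sigma
  tied <- vals <= min(vals) + 1e-10
  best <- fits[tied][[order(conv[tied], sig[tied])[1]]]
  if (best$convergence != 0) {
    # L-BFGS-B can end its line search abnormally at near-zero RMSE;
    # polish with a derivative-free pass before reporting failure
    clamped <- function(par)
      rmse_of(pmin(pmax(par, lower), upper))
    polish <- stats::optim(best$par, clamped, method = "Nelder-Mead")
    if (polish$value <= best$value + 1e-12) {
      polish$par <- pmin(pmax(polish$par, lower), upper)
      best <- polish
    }
  }
  if (best$convergence != 0)
    warning("optimizer reported non-convergence (code ",
            best$convergence, ")")
  out <- permafrost_params(envelope, mu = best$par[1], sigma = best$par[2],
                           f_max = best$par[3])
  attr(out, "rmse") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Project equilibrium permafrost peatland extent under warming
#'
#' For each global warming stabilization level `dT` (degrees C above
#' preindustrial), cell MAAT is shifted by `amplification * (dT - 0.5)` --
#' the mapped climate is taken to be in quasi-equilibrium with the
#' present-day +0.5 degree world -- and the equilibrium permafrost peatland
#' extent is the peat-area-weighted sum of the curve evaluated at the
#' shifted MAAT. Also returns, per cell, the lowest warming level at which
#' the equilibrium fraction first drops below `threshold` (the "<10%
#' permafrost" mapping convention).
#'
#' @param grid a [landscape_grid] object.
#' @param warming_levels warming stabilization levels, degrees C in `[0, 6]`.
#' @param amplification unitless ratio of regional to global warming
#'   (uniform polar amplification; default 2).
#' @param params_set named list of [permafrost_params()] objects; extents
#'   are reported for each (typically central/lower/upper envelopes).
#' @param apply_cap apply the +1 degree C warm cutoff (default `TRUE`).
#' @param threshold fraction below which a cell counts as having lost its
#'   permafrost, for the threshold map.
#' @return an object of class `"extent_projection"`: a list with `table`
#'   (data frame of warming level and extent in million km2 per envelope)
#'   and `threshold_dT` (per-cell warming level of permafrost loss, NA where
#'   never reached or no peat).
#' @export
project_permafrost_extent <- function(grid,
                                      warming_levels = seq(0.5, 6, by = 0.5),
                                      amplification = 2,
                                      params_set = list(
                                        central = permafrost_params("central"),
                                        lower   = permafrost_params("lower"),
                                        upper   = permafrost_params("upper")),
                                      apply_cap = TRUE,
                                      threshold = 0.10) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (any(warming_levels < 0 | warming_levels > 6))
    stop("warming levels must lie in [0, 6] degrees C")
  a_peat <- grid$cell_area * grid$peat_fraction   # km2 of peat per cell
  tab <- data.frame(warming = warming_levels)
  for (nm in names(params_set)) {
    tab[[paste0("extent_", nm)]] <- vapply(warming_levels, function(dT) {
      f <- permafrost_fraction(grid$maat + amplification * (dT - 0.5),
                               params_set[[nm]], apply_cap = apply_cap)
      sum(a_peat * f) / 1e6                       # million km2
    }, numeric(1))
  }
  central <- params_set[[1]]
  thr <- rep(NA_real_, length(grid$maat))
  for (dT in sort(warming_levels)) {
    f <- permafrost_fraction(grid$maat + amplification * (dT - 0.5),
                             central, apply_cap = apply_cap)
    hit <- is.na(thr) & f < threshold & grid$peat_fraction > 0
    thr[hit] <- dT
  }
  structure(list(table = tab, threshold_dT = thr,
                 amplification = amplification),
            class = "extent_projection")
}

#' @export
print.extent_projection <- function(x, ...) {
  cat("Equilibrium permafrost peatland extent (million km2):\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

# Save/restore the global RNG state so internal seeded draws do not
# disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
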