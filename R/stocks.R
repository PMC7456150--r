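#' Depth-to-storage linear model parameters
#'
#' Linear coefficients relating peat depth (cm) to organic C and total N
#' storage (kg m-2). The C model is shared across permafrost classes; the
#' N model is class-specific because N storages differ more than twofold
#' between permafrost and permafrost-free peat at similar depths. Default
#' slopes reproduce the inventory's class-mean storages at class-mean
#' depths (C: 115/249 overall; N: 1.9/286 permafrost-free, 4.2/205
#' permafrost) with zero intercepts. Predictions are clipped at zero.
#'
#' @param slope_c,intercept_c C model, kg C m-2 per cm and kg C m-2.
#' @param slope_n_free,intercept_n_free N model, permafrost-free class.
#' @param slope_n_perm,intercept_n_perm N model, permafrost class.
#' @return an object of class `"storage_params"`.
#' @export
storage_params <- function(slope_c = 115 / 249, intercept_c = 0,
                           slope_n_free = 1.9 / 286, intercept_n_free = 0,
                           slope_n_perm = 4.2 / 205, intercept_n_perm = 0) {
  if (slope_c <= 0 || slope_n_free <= 0 || slope_n_perm <= 0)
    stop("slopes must be positive")
  structure(list(slope_c = slope_c, intercept_c = intercept_c,
                 slope_n_free = slope_n_free,
                 intercept_n_free = intercept_n_free,
                 slope_n_perm = slope_n_perm,
                 intercept_n_perm = intercept_n_perm),
            class = "storage_params")
}

#' Fit depth-to-storage models from peat cores
#'
#' Ordinary least squares of storage on depth. The C model pools all cores
#' with `c_storage`; N models are fitted per permafrost class when enough
#' cores carry `n_storage` (falling back to the defaults of
#' [storage_params()] otherwise).
#'
#' @param cores a `peat_cores` data frame (needs `depth_cm`, `c_storage`;
#'   optionally `n_storage` and logical `permafrost`).
#' @return a [storage_params()] object with attributes `residual_sd_c`,
#'   `r_squared_c` and `n_cores_c`.
#' @export
fit_storage_model <- function(cores) {
  stopifnot(is.data.frame(cores))
  cc <- cores[is.finite(cores$depth_cm) & is.finite(cores$c_storage), ]
  if (nrow(cc) < 2) stop("need at least 2 cores with C storage")
  if (stats::sd(cc$depth_cm) == 0)
    stop("all depths identical: singular fit")
  fc <- stats::lm(c_storage ~ depth_cm, data = cc)
  p <- storage_params(slope_c = stats::coef(fc)[["depth_cm"]],
                      intercept_c = stats::coef(fc)[["(Intercept)"]])
  if (!is.null(cores$n_storage) && !is.null(cores$permafrost)) {
    for (cls in c(TRUE, FALSE)) {
      cn <- cores[!is.na(cores$n_storage) & cores$permafrost == cls, ]
      if (nrow(cn) >= 3 && stats::sd(cn$depth_cm) > 0) {
        fn <- stats::lm(n_storage ~ depth_cm, data = cn)
        if (stats::coef(fn)[["depth_cm"]] > 0) {
          if (cls) {
            p$slope_n_perm <- stats::coef(fn)[["depth_cm"]]
            p$intercept_n_perm <- stats::coef(fn)[["(Intercept)"]]
          } else {
            p$slope_n_free <- stats::coef(fn)[["depth_cm"]]
            p$intercept_n_free <- stats::coef(fn)[["(Intercept)"]]
          }
        }
      }
    }
  }
  attr(p, "residual_sd_c") <- stats::sigma(fc)
  attr(p, "r_squared_c") <- suppressWarnings(summary(fc)$r.squared)
  attr(p, "n_cores_c") <- nrow(cc)
  p
}

#' Predict peat C or N storage from depth
#'
#' `max(0, slope * depth + intercept)` with the class-appropriate
#' coefficients.
#'
#' @param depth peat depth, cm (vectorised; must be non-negative).
#' @param params a [storage_params()] object.
#' @param what `"c"` or `"n"`.
#' @param permafrost logical; selects the N model class (ignored for C).
#' @return storage in kg m-2.
#' @examples
#' predict_storage(249, storage_params())             # ~115 kg C m-2
#' predict_storage(205, storage_params(), "n", TRUE)  # ~4.2 kg N m-2
#' @export
predict_storage <- function(depth, params = storage_params(),
                            what = c("c", "n"), permafrost = FALSE) {
  what <- match.arg(what)
  if (any(depth < 0)) stop("depth must be non-negative")
  stopifnot(inherits(params, "storage_params"))
  if (what == "c") {
    pmax(0, params$slope_c * depth + params$intercept_c)
  } else if (permafrost) {
    pmax(0, params$slope_n_perm * depth + params$intercept_n_perm)
  } else {
    pmax(0, params$slope_n_free * depth + params$intercept_n_free)
  }
}

#' Area-weighted peatland C and N stock summary
#'
#' Aggregates a landscape into the standard inventory table: peat area,
#' area-weighted mean depth, mean C and N storages, and total C and N
#' stocks, reported for all peatlands and for the permafrost-free and
#' permafrost-affected classes. The permafrost-affected portion of each
#' cell is `peat_fraction * permafrost_fraction`; the remainder is
#' permafrost-free. Totals are in Pg (1e12 kg).
#'
#' @param grid a [landscape_grid] object.
#' @return an object of class `"stock_summary"`: a data frame with rows
#'   `all`, `permafrost_free`, `permafrost` and columns `area_mkm2`,
#'   `depth_cm`, `c_storage_kg_m2`, `c_stock_pg`, `n_storage_kg_m2`,
#'   `n_stock_pg`.
#' @export
aggregate_stocks <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  len <- vapply(grid[c("maat", "peat_fraction", "permafrost_fraction",
                       "peat_depth", "c_storage", "n_storage")],
                length, integer(1))
  if (length(unique(len)) != 1) stop("mismatched grid field lengths")

  a_m2 <- grid$cell_area * 1e6 * grid$peat_fraction    # m2 of peat
  w <- list(all = a_m2,
            permafrost_free = a_m2 * (1 - grid$permafrost_fraction),
            permafrost = a_m2 * grid$permafrost_fraction)
  row <- function(wt) {
    A <- sum(wt)
    data.frame(
      area_mkm2 = A / 1e12,                            # m2 -> Mkm2
      depth_cm = if (A > 0) sum(wt * grid$peat_depth) / A else NA_real_,
      c_storage_kg_m2 = if (A > 0) sum(wt * grid$c_storage) / A else NA_real_,
      c_stock_pg = sum(wt * grid$c_storage) / 1e12,    # kg -> Pg
      n_storage_kg_m2 = if (A > 0) sum(wt * grid$n_storage) / A else NA_real_,
      n_stock_pg = sum(wt * grid$n_storage) / 1e12)
  }
  out <- do.call(rbind, lapply(w, row))
  rownames(out) <- names(w)
  class(out) <- c("stock_summary", "data.frame")
  out
}

#' @export
print.stock_summary <- function(x, ...) {
  cat("Peatland C and N stock summary (area-weighted):\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Spatially weighted trimmed RMSE
#'
#' RMSE of residuals (observed minus predicted) after discarding residuals
#' below their 5th and above their 95th percentile, with supplied weights
#' renormalised over the kept residuals. This is the uncertainty statistic
#' reported alongside the stock tables.
#'
#' @param observed,predicted numeric vectors of equal length (>= 20).
#' @param weights optional non-negative weights (default: equal).
#' @param trim lower/upper percentile cut points.
#' @return the trimmed, weighted RMSE (a single non-negative number).
#' @export
trimmed_rmse <- function(observed, predicted, weights = NULL,
                         trim = c(0.05, 0.95)) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 20) stop("need at least 20 pairs")
  if (is.null(weights)) weights <- rep(1, length(observed))
  if (length(weights) != length(observed))
    stop("'weights' must match the data length")
  r <- observed - predicted
  q <- stats::quantile(r, trim, names = FALSE)
  keep <- r >= q[1] & r <= q[2]
  w <- weights[keep] / sum(weights[keep])
  sqrt(sum(w * r[keep]^2))
}

#' Combine northern stocks with tropical and southern estimates
#'
#' @param summary a [aggregate_stocks()] result (its `all` C stock is the
#'   northern total), or a single number of Pg C.
#' @param tropical_pg,southern_pg literature C stocks for tropical and
#'   extratropical southern peatlands, Pg C.
#' @return list with `northern_pg`, `global_pg`, `northern_share`
#'   (NA with a warning when the global total is zero).
#' @examples
#' global_stock_report(415)  # global 535, northern share ~0.78
#' @export
global_stock_report <- function(summary, tropical_pg = 105,
                                southern_pg = 15) {
  northern <- if (inherits(summary, "stock_summary"))
    summary["all", "c_stock_pg"] else as.numeric(summary)
  if (northern < 0 || tropical_pg < 0 || southern_pg < 0)
    stop("stocks must be non-negative")
  globe <- northern + tropical_pg + southern_pg
  share <- if (globe > 0) northern / globe else {
    warning("global stock is zero: northern share undefined")
    NA_real_
  }
  list(northern_pg = northern, global_pg = globe, northern_share = share)
}
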