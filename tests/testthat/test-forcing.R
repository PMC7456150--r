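# Present-day regional budget used across forcing tests (Pg C/y, Tg N/y).
present_day_flux <- function(horizon = 500) {
  flux_series(0:horizon, co2_pgc = -0.10, ch4_pgc = 0.026,
              n2o_tgn = 0.022)
}

test_that("zero flux produces zero burden and zero forcing", {
  f <- flux_series(0:100)
  b <- burden_perturbation(f)
  expect_true(all(b$co2_ppm == 0 & b$ch4_ppb == 0 & b$n2o_ppb == 0))
  rf <- forcing_from_flux(f)
  expect_true(all(rf$rf_net == 0))
  expect_equal(rf$rf_net, rf$rf_co2 + rf$rf_ch4 + rf$rf_n2o)
})

test_that("perturbation starts at zero and a sustained flux reaches the F*tau steady state", {
  cst <- forcing_constants()
  f <- flux_series(0:400, ch4_pgc = 0.012)   # CH4 only
  b <- burden_perturbation(f, cst)
  expect_equal(b$ch4_ppb[1], 0)
  F_ppb <- 0.012 * 1e3 * (16 / 12) / cst$tg_per_ppb_ch4  # ppb per year
  at_10tau <- b$ch4_ppb[b$time == ceiling(10 * cst$ch4_tau)]
  expect_lt(abs(at_10tau - F_ppb * cst$ch4_tau) / (F_ppb * cst$ch4_tau),
            0.01)
  # same for the long-lived gas at its own 10 tau
  f2 <- flux_series(0:1300, n2o_tgn = 0.5)
  b2 <- burden_perturbation(f2, cst)
  F2 <- 0.5 * (44 / 28) / cst$tg_per_ppb_n2o
  at2 <- b2$n2o_ppb[b2$time == 1210]
  expect_lt(abs(at2 - F2 * cst$n2o_tau) / (F2 * cst$n2o_tau), 0.01)
})

test_that("a unit CO2 pulse reproduces the impulse-response function", {
  cst <- forcing_constants()
  co2 <- c(1, rep(0, 300))                  # 1 Pg C emitted in year one
  f <- flux_series(0:300, co2_pgc = co2)
  b <- burden_perturbation(f, cst)
  # closed-form oracle at the midpoint-lag convention
  irf <- function(l) 0.2173 + 0.2240 * exp(-l / 394.4) +
    0.2824 * exp(-l / 36.54) + 0.2763 * exp(-l / 4.304)
  t <- b$time[-1]
  expect_equal(b$co2_ppm[-1], irf(t - 0.5) / cst$pgc_per_ppm_co2,
               tolerance = 1e-12)
})

test_that("the convolution engine agrees with brute-force double-loop summation", {
  set.seed(77)
  cst <- forcing_constants()
  f <- flux_series(0:99, co2_pgc = rnorm(100, 0, 0.1),
                   ch4_pgc = runif(100, 0, 0.05),
                   n2o_tgn = rnorm(100, 0, 0.02))
  b <- burden_perturbation(f, cst)
  # independent brute force with explicit loops
  brute <- function(mass, kern) {
    n <- length(mass)
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      if (i > 1) for (j in 1:(i - 1)) acc <- acc + mass[j] *
          kern(i - j - 0.5)
      out[i] <- acc
    }
    out
  }
  m_ch4 <- f$ch4_pgc * 1e3 * (16 / 12) / cst$tg_per_ppb_ch4
  expect_equal(b$ch4_ppb, brute(m_ch4, function(l) exp(-l / 12.4)),
               tolerance = 1e-12)
  irf <- function(l) 0.2173 + 0.2240 * exp(-l / 394.4) +
    0.2824 * exp(-l / 36.54) + 0.2763 * exp(-l / 4.304)
  expect_equal(b$co2_ppm, brute(f$co2_pgc / cst$pgc_per_ppm_co2, irf),
               tolerance = 1e-12)
})

test_that("forcing is linear in flux magnitude", {
  f1 <- present_day_flux(200)
  f3 <- flux_series(0:200, co2_pgc = -0.30, ch4_pgc = 0.078,
                    n2o_tgn = 0.066)
  rf1 <- forcing_from_flux(f1)
  rf3 <- forcing_from_flux(f3)
  expect_equal(rf3$rf_net, 3 * rf1$rf_net, tolerance = 1e-12)
})

test_that("peak and crossover diagnostics handle edge cases", {
  mono <- data.frame(time = 0:9, rf_net = -(1:10))
  d <- peak_and_crossover(mono)
  expect_equal(d$peak_time, 0)
  expect_false(d$crossed)
  expect_true(is.na(d$crossover_time))
  toy <- data.frame(time = 0:2, rf_net = c(1, 2, -1))
  d2 <- peak_and_crossover(toy)
  expect_equal(d2$peak_wm2, 2)
  expect_equal(d2$peak_time, 1)
  expect_true(d2$crossover_time > 1 && d2$crossover_time < 2)
  expect_equal(d2$crossover_time, 1 + 2 / 3, tolerance = 1e-12)
})

test_that("the sustained present-day budget warms for decades then cools", {
  rf <- forcing_from_flux(present_day_flux(500))
  d <- peak_and_crossover(rf)
  expect_gte(d$peak_time, 30)
  expect_lte(d$peak_time, 40)
  expect_gt(rf$rf_net[rf$time == 50], 0)
  expect_lt(rf$rf_net[rf$time == 500], 0)
})

test_that("halving the time step changes the peak by less than 1%", {
  f1 <- present_day_flux(200)
  f05 <- flux_series(seq(0, 200, by = 0.5), co2_pgc = -0.10,
                     ch4_pgc = 0.026, n2o_tgn = 0.022)
  p1 <- max(forcing_from_flux(f1)$rf_net)
  p05 <- max(forcing_from_flux(f05)$rf_net)
  expect_lt(abs(p1 - p05) / p05, 0.01)
})

test_that("comparison against an anthropogenic trajectory behaves and flags bad input", {
  rf <- forcing_from_flux(present_day_flux(100))
  same <- data.frame(time = rf$time, rf_wm2 = rf$rf_net)
  same$rf_wm2[same$rf_wm2 <= 0] <- 1       # keep strictly positive
  rf_pos <- rf; rf_pos$rf_net <- same$rf_wm2
  cmp <- compare_to_anthropogenic(rf_pos, same)
  expect_equal(cmp$ratio_pct, rep(100, nrow(cmp)))
  zero <- rf_pos; zero$rf_net <- 0
  expect_equal(compare_to_anthropogenic(zero, same)$ratio_pct,
               rep(0, nrow(cmp)))
  neg <- same; neg$rf_wm2[5] <- -1
  expect_warning(out <- compare_to_anthropogenic(rf_pos, neg),
                 "non-positive")
  expect_true(any(is.na(out$ratio_pct)))
})

test_that("non-uniform time grids and bad constants are rejected", {
  expect_error(flux_series(c(0, 1, 3)), "uniform")
  expect_error(forcing_constants(co2_amps = c(0.5, 0.5, 0.1),
                                 co2_taus = c(Inf, 100, 10)), "sum to 1")
  expect_error(forcing_constants(ch4_tau = -1), "positive")
})
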