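test_that("chronosequence loss fraction follows the clamped power law", {
  # direct high-precision evaluation: 1.1451 * exp(-0.0771 * log(100))
  oracle_100 <- 1.1451 * exp(-0.0771 * log(100))
  expect_equal(loss_fraction_100y(100), oracle_100, tolerance = 1e-12)
  expect_equal(loss_fraction_100y(100), 0.803, tolerance = 1e-3)
  # clamp boundary x* = a^(-1/b) ~ 5.797
  xstar <- 1.1451^(1 / 0.0771)
  expect_equal(xstar, 5.797, tolerance = 1e-3)
  expect_equal(loss_fraction_100y(xstar * 0.999), 1)
  expect_lt(loss_fraction_100y(xstar * 1.001), 1)
  # monotone decay toward zero for large stocks
  x <- 10^seq(1, 8)
  f <- loss_fraction_100y(x)
  expect_true(all(diff(f) < 0))
  expect_lt(f[length(f)], 0.35)
  expect_error(loss_fraction_100y(0), "positive")
})

test_that("deterministic stage schedule has boundaries at 50 and 150 years", {
  s <- stage_schedule(onset = 0, tk_fraction = 1)
  expect_equal(s$active_layer_deepening[s$year == 49], 1)
  expect_equal(s$young_thermokarst[s$year == 50], 1)
  expect_equal(s$young_thermokarst[s$year == 149], 1)
  expect_equal(s$stabilized[s$year == 150], 1)
})

test_that("stage occupancies always sum to one and onset translates the schedule", {
  for (seed in 1:4) {
    s <- stage_schedule(onset = 7.5, mode = "sampled", seed = seed)
    tot <- s$intact + s$active_layer_deepening + s$young_thermokarst +
      s$stabilized
    expect_equal(tot, rep(1, nrow(s)), tolerance = 1e-12)
  }
  s0 <- stage_schedule(onset = 0, horizon = 300)
  s20 <- stage_schedule(onset = 20, horizon = 320)
  for (v in c("active_layer_deepening", "young_thermokarst", "stabilized"))
    expect_equal(s20[[v]][s20$year >= 20], s0[[v]][s0$year < 300])
  expect_error(stage_schedule(onset = -1), "non-negative")
})

test_that("N losses scale from C losses by class C:N ratios", {
  tab <- cn_ratio_table()
  r_perm <- tab$boreal[tab$status == "permafrost"]
  expect_equal(r_perm, 108 / 4.2)           # ~25.7
  expect_equal(scale_n_losses(r_perm, status = "permafrost"), 1)
  r_free <- tab$boreal[tab$status == "nonpermafrost"]
  expect_equal(r_free, 123 / 1.9, tolerance = 1e-12)  # ~64.7
  expect_equal(scale_n_losses(123, status = "nonpermafrost"), 1.9,
               tolerance = 1e-12)
  expect_error(scale_n_losses(1, status = "thawed"), "unknown status")
  expect_error(scale_n_losses(1, biome = "desert"), "unknown biome")
  expect_error(scale_n_losses(-1), "non-negative")
})

test_that("warming at the present-day anchor produces a null scenario", {
  g <- small_landscape()
  sc <- run_thaw_scenario(g, 0.5)
  expect_equal(sc$totals$thawed_area_mkm2, 0)
  expect_equal(max(abs(sc$series$co2_pgc)), 0)
  expect_equal(max(abs(sc$series$ch4_pgc)), 0)
  expect_equal(max(abs(sc$series$lateral_c_pgc)), 0)
  expect_error(run_thaw_scenario(g, 0.2), "\\[0.5, 6\\]")
  expect_error(run_thaw_scenario(g, 6.5), "\\[0.5, 6\\]")
})

test_that("the old-carbon ledger closes to machine precision", {
  for (seed in c(3, 9)) {
    g <- small_landscape(seed = seed)
    sc <- run_thaw_scenario(g, 2 + seed / 10)
    s <- sc$series
    # direct-summation oracle for the pool trajectory
    recomputed <- sc$totals$initial_old_c_pg -
      cumsum(s$old_gaseous_pgc) - cumsum(s$old_lateral_pgc)
    expect_equal(s$old_c_pg, recomputed,
                 tolerance = 1e-9 * sc$totals$initial_old_c_pg)
    # final-year closure
    resid <- sc$totals$initial_old_c_pg -
      (s$old_c_pg[nrow(s)] + sum(s$old_gaseous_pgc) +
         sum(s$old_lateral_pgc))
    expect_lt(abs(resid) / sc$totals$initial_old_c_pg, 1e-9)
  }
})

test_that("stage areas partition the peatland area every year", {
  g <- small_landscape()
  sc <- run_thaw_scenario(g, 3)
  s <- sc$series
  total <- s$area_intact_km2 + s$area_ald_km2 + s$area_thermokarst_km2 +
    s$area_stabilized_km2
  a_peat <- sum(g$cell_area * g$peat_fraction)
  expect_equal(total, rep(a_peat, nrow(s)), tolerance = 1e-9)
})

test_that("cumulative carbon loss grows with the warming level", {
  g <- small_landscape()
  lat <- vapply(c(1, 2, 4, 6), function(w)
    run_thaw_scenario(g, w)$totals$cum_lateral_old_pg, numeric(1))
  expect_true(all(diff(lat) > 0))
})

test_that("zeroing the loss coefficient removes lateral losses but not stage GHG fluxes", {
  g <- small_landscape()
  cfg0 <- thaw_config(loss = loss_model(a = 0))
  sc0 <- run_thaw_scenario(g, 2, cfg0)
  sc1 <- run_thaw_scenario(g, 2)
  expect_equal(sc0$totals$cum_lateral_old_pg, 0)
  expect_equal(sc0$series$ch4_pgc, sc1$series$ch4_pgc)
  expect_equal(sc0$series$old_gaseous_pgc, sc1$series$old_gaseous_pgc)
})

test_that("deterministic mode equals the expectation of sampled mode", {
  g <- generate_landscape(synth_config(nrow = 20, ncol = 15, seed = 4))
  det <- run_thaw_scenario(g, 2)$totals$cum_net_ch4_pg
  draws <- vapply(1:500, function(s)
    run_thaw_scenario(g, 2, thaw_config(mode = "sampled",
                                        seed = s))$totals$cum_net_ch4_pg,
    numeric(1))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - det), 4 * mc_se + 1e-6 * abs(det))
})

test_that("lateral losses per thawed area fall in the observed 11-18 kg C/m2 band", {
  sc <- run_thaw_scenario(default_landscape(), 2)
  expect_gte(sc$totals$lateral_per_thawed_m2_kg, 11)
  expect_lte(sc$totals$lateral_per_thawed_m2_kg, 18)
})
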