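test_that("OLS storage fit matches the closed-form estimator and recovers the generating slope", {
  set.seed(42)
  depth <- runif(300, 50, 450)
  storage <- 0.462 * depth + rnorm(300, 0, 5)
  cores <- data.frame(depth_cm = depth, c_storage = storage)
  fit <- fit_storage_model(cores)
  # closed-form OLS oracle
  slope_oracle <- cov(depth, storage) / var(depth)
  int_oracle <- mean(storage) - slope_oracle * mean(depth)
  expect_equal(fit$slope_c, slope_oracle, tolerance = 1e-10)
  expect_equal(fit$intercept_c, int_oracle, tolerance = 1e-8)
  expect_lt(abs(fit$slope_c - 0.462), 0.02)
})

test_that("two cores give the exact interpolating line and zero noise gives R2 = 1", {
  two <- data.frame(depth_cm = c(100, 300), c_storage = c(50, 150))
  fit <- fit_storage_model(two)
  expect_equal(fit$slope_c, 0.5)
  expect_equal(fit$intercept_c, 0)
  exact <- data.frame(depth_cm = seq(50, 400, by = 50),
                      c_storage = 0.4 * seq(50, 400, by = 50) + 10)
  expect_equal(attr(fit_storage_model(exact), "r_squared_c"), 1)
  expect_error(fit_storage_model(data.frame(depth_cm = rep(100, 5),
                                            c_storage = 1:5)),
               "singular")
})

test_that("storage predictions hit the class-mean anchors and clip at zero", {
  p <- storage_params()
  expect_equal(predict_storage(0, storage_params(intercept_c = 0)), 0)
  expect_equal(predict_storage(249, p), 115, tolerance = 1e-6)
  expect_equal(predict_storage(205, p, "n", permafrost = TRUE), 4.2,
               tolerance = 1e-6)
  expect_equal(predict_storage(286, p, "n", permafrost = FALSE), 1.9,
               tolerance = 1e-6)
  expect_equal(predict_storage(10, storage_params(intercept_c = -100)), 0)
  expect_error(predict_storage(-1, p), "non-negative")
})

test_that("predicted storage is monotone non-decreasing in depth", {
  d <- seq(0, 600, by = 10)
  expect_true(all(diff(predict_storage(d, storage_params())) >= 0))
  expect_true(all(diff(predict_storage(d, storage_params(), "n",
                                       TRUE)) >= 0))
})

test_that("stock aggregation does the area and unit arithmetic", {
  g <- make_grid(maat = -5, peat_fraction = 0.4, cell_area = 25,
                 c_storage = 100)
  s <- aggregate_stocks(g)
  # 25 km2 * 0.4 * 100 kg/m2 = 1e9 kg = 0.001 Pg
  expect_equal(s["all", "c_stock_pg"], 0.001)
  expect_equal(s["all", "area_mkm2"], 25 * 0.4 / 1e6)
  # kg m-2 -> Pg and back inverts exactly
  expect_equal(s["all", "c_stock_pg"] * 1e12 /
                 (s["all", "area_mkm2"] * 1e12),
               s["all", "c_storage_kg_m2"])
})

test_that("permafrost-free landscapes put zero stock in the permafrost class", {
  g <- make_grid(maat = c(-5, 0, 5), peat_fraction = 0.5,
                 permafrost_fraction = 0)
  s <- aggregate_stocks(g)
  expect_equal(s["permafrost", "c_stock_pg"], 0)
  expect_equal(s["permafrost", "area_mkm2"], 0)
  expect_equal(s["permafrost_free", "c_stock_pg"],
               s["all", "c_stock_pg"])
})

test_that("class totals and cell partitions are additive", {
  g <- small_landscape(seed = 3)
  s <- aggregate_stocks(g)
  expect_equal(s["permafrost", "c_stock_pg"] +
                 s["permafrost_free", "c_stock_pg"],
               s["all", "c_stock_pg"], tolerance = 1e-9)
  idx <- seq_along(g$maat)
  half <- idx[idx %% 2 == 0]
  s1 <- aggregate_stocks(subset_grid(g, half))
  s2 <- aggregate_stocks(subset_grid(g, setdiff(idx, half)))
  expect_equal(s1["all", "c_stock_pg"] + s2["all", "c_stock_pg"],
               s["all", "c_stock_pg"], tolerance = 1e-9)
  expect_equal(s1["all", "n_stock_pg"] + s2["all", "n_stock_pg"],
               s["all", "n_stock_pg"], tolerance = 1e-9)
})

test_that("trimmed RMSE discards the percentile tails and honours weights", {
  expect_equal(trimmed_rmse(rep(1, 50), rep(1, 50)), 0)
  # 90 residuals of +-1, 10 outliers of +-100 placed in the trimmed tails
  res <- c(rep(c(-1, 1), 45), rep(-100, 5), rep(100, 5))
  obs <- res; pred <- rep(0, 100)
  # brute-force oracle: sort, cut at the same percentile rule, plain RMSE
  q <- quantile(res, c(0.05, 0.95), names = FALSE)
  kept <- res[res >= q[1] & res <= q[2]]
  expect_equal(trimmed_rmse(obs, pred), sqrt(mean(kept^2)))
  expect_equal(trimmed_rmse(obs, pred), 1.0)
  # unit weights equal the unweighted statistic
  set.seed(1)
  o <- rnorm(60); p <- rnorm(60)
  expect_equal(trimmed_rmse(o, p, weights = rep(1, 60)),
               trimmed_rmse(o, p))
  expect_error(trimmed_rmse(1:30, 1:29), "equal length")
  expect_error(trimmed_rmse(1:10, 1:10), "at least 20")
})

test_that("global stock report combines northern, tropical and southern pools", {
  rep1 <- global_stock_report(415, 105, 15)
  expect_equal(rep1$global_pg, 535)
  expect_equal(rep1$northern_share, 415 / 535, tolerance = 1e-12)
  expect_warning(rep0 <- global_stock_report(0, 0, 0), "undefined")
  expect_true(is.na(rep0$northern_share))
  expect_equal(global_stock_report(100, 0, 0)$northern_share, 1)
  expect_error(global_stock_report(-1), "non-negative")
})
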