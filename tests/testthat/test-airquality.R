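test_that("equilibrium handles the limiting cases exactly", {
  airq <- nh3_params()$airq
  # no ammonia: no ammonium, no particulate nitrate
  st <- equilibrium_pm(0, 10, 12, 280, 0.7, airq)
  expect_equal(st$nh4, 0)
  expect_equal(st$no3, 0)
  expect_equal(st$pm25_inorganic, 10)
  expect_equal(st$hno3_gas, 12 / 62.004 * 63.01, tolerance = 1e-12)

  # ammonia exactly at the sulfate demand, no nitrate: all in particle phase
  s <- 9.606  # 0.1 umol SO4
  nh3 <- 2 * (s / 96.06) * 17.031
  st2 <- equilibrium_pm(nh3, s, 0, 280, 0.7, airq)
  expect_equal(st2$nh3_gas, 0, tolerance = 1e-12)
  expect_equal(st2$nh4, 0.2 * 18.039, tolerance = 1e-12)

  expect_error(equilibrium_pm(-1, 1, 1, 280, 0.7, airq), "total_nh3")
  expect_error(equilibrium_pm(1, 1, 1, 400, 0.7, airq), "physical range")
})

test_that("equilibrium conserves nitrogen and nitrate to 1e-9", {
  airq <- nh3_params()$airq
  set.seed(12)
  nh3 <- runif(500, 0, 40)
  so4 <- runif(500, 0, 25)
  no3 <- runif(500, 0, 30)
  tk <- runif(500, 250, 310)
  rh <- runif(500, 0.2, 0.95)
  st <- equilibrium_pm(nh3, so4, no3, tk, rh, airq)
  n_in <- nh3 / 17.031
  n_out <- st$nh3_gas / 17.031 + st$nh4 / 18.039
  expect_equal(n_out, n_in, tolerance = 1e-9)
  no3_in <- no3 / 62.004
  no3_out <- st$hno3_gas / 63.01 + st$no3 / 62.004
  expect_equal(no3_out, no3_in, tolerance = 1e-9)
  expect_true(all(st$nh3_gas >= -1e-12 & st$hno3_gas >= -1e-12 &
                    st$nh4 >= 0 & st$no3 >= 0))
})

test_that("PM response to ammonia is monotone, flat when rich, steep after", {
  airq <- nh3_params()$airq
  so4 <- 8; no3 <- 12; tk <- 278; rh <- 0.75
  grid <- seq(0, 40, by = 0.25)
  pm <- equilibrium_pm(grid, so4, no3, tk, rh, airq)$pm25_inorganic
  expect_true(all(diff(pm) >= -1e-12))
  # NH3-rich: a 10% cut changes PM by < 1%
  rich <- 40
  pm0 <- equilibrium_pm(rich, so4, no3, tk, rh, airq)$pm25_inorganic
  pm1 <- equilibrium_pm(0.9 * rich, so4, no3, tk, rh, airq)$pm25_inorganic
  expect_lt((pm0 - pm1) / pm0, 0.01)
  # concavity: the 40->50% cut removes more PM than the first 10% cut
  d_first <- pm0 - pm1
  d_mid <- equilibrium_pm(0.6 * rich, so4, no3, tk, rh, airq)$pm25_inorganic -
    equilibrium_pm(0.5 * rich, so4, no3, tk, rh, airq)$pm25_inorganic
  expect_gt(d_mid, d_first)
})

test_that("gridded PM response is zero for an unchanged field and monotone", {
  r <- small_region(seed = 51)
  base <- total_inventory(r)
  resp0 <- pm_response(base, base, r)
  expect_equal(resp0$by_cell_month$d_pm, rep(0, nrow(resp0$by_cell_month)))

  sc <- build_scenario("NM", r, base)
  resp <- pm_response(base, sc$emissions, r)
  expect_true(all(resp$by_cell_month$d_pm >= -1e-9))
  expect_gt(resp$summary$pct_reduction_pop, 0)

  short <- base[-(1:5), ]
  expect_error(pm_response(base, short, r), "different grids")
})

test_that("an additional acid-precursor cut lowers PM further", {
  airq <- nh3_params()$airq
  pm_full <- equilibrium_pm(10, 8, 12, 278, 0.75, airq)$pm25_inorganic
  pm_cut <- equilibrium_pm(10, 0.8 * 8, 0.8 * 12, 278, 0.75,
                           airq)$pm25_inorganic
  expect_lt(pm_cut, pm_full)
})

test_that("control efficiency is the ratio of percentage reductions", {
  expect_equal(round(control_efficiency(19.2, 48.3), 2), 0.40)
  expect_equal(round(control_efficiency(22.8, 58.2), 2), 0.39)
  expect_equal(control_efficiency(0, 30), 0)
  expect_error(control_efficiency(5, 0), "pct_nh3_reduction")
})

test_that("polluted days use a strict 150 threshold", {
  expect_equal(polluted_day_frequency(rep(149.9, 30)), 0)
  expect_equal(polluted_day_frequency(c(200, 100, 151)), 2)
  expect_equal(polluted_day_frequency(c(150, 150.0001)), 1)
  expect_equal(polluted_day_change(100, 39), 61)
  expect_error(polluted_day_frequency(numeric()), "empty")
})

test_that("sub-grid concentration produces a monotone underestimation curve", {
  out <- subgrid_experiment(concentration_levels = c(100, 25, 4, 1))
  expect_equal(out$underestimation_pct[out$k == 100], 0)
  u <- out$underestimation_pct[order(-out$k)]
  expect_true(all(diff(u) >= -1e-9))
  expect_gt(out$underestimation_pct[out$k == 1],
            out$underestimation_pct[out$k == 25])

  # without deposition there is no loss mechanism at any concentration
  p0 <- nh3_params()
  p0$airq$dry_deposition_velocity <- 0
  out0 <- subgrid_experiment(concentration_levels = c(100, 10, 1), params = p0)
  expect_equal(out0$underestimation_pct, rep(0, 3), tolerance = 1e-12)

  expect_error(subgrid_experiment(concentration_levels = 0), "n_boxes")
  expect_error(subgrid_experiment(concentration_levels = 101), "n_boxes")
})
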