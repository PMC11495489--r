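test_that("fertilizer emissions follow the EF identity and stay linear", {
  # hand oracle: 100 kg N/ha x 1000 ha x 0.12 x 17/14 = 14571.43 kg
  e <- fertilizer_emissions(100, 1000, 0.12)
  expect_equal(sum(e), 100 * 1000 * 0.12 * 17 / 14, tolerance = 1e-12)
  expect_length(e, 12)

  expect_equal(fertilizer_emissions(0, 1000, 0.12), rep(0, 12))
  # doubling the EF doubles every monthly value
  temp <- 10 + 12 * cos(2 * pi * (1:12 - 7) / 12)
  e1 <- fertilizer_emissions(50, 200, 0.1, temp_c = temp,
                             temperature_sensitivity = 0.05)
  e2 <- fertilizer_emissions(50, 200, 0.2, temp_c = temp,
                             temperature_sensitivity = 0.05)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # warm months carry more with positive sensitivity
  expect_gt(e1[7], e1[1])

  expect_error(fertilizer_emissions(-5, 10, 0.1), "n_rate")
  expect_error(fertilizer_emissions(5, 10, 1.4), "ef")
  expect_error(
    fertilizer_emissions(5, 10, 0.1, monthly_weights = rep(0.2, 12)),
    "sum to 1")
})

test_that("livestock emissions scale with pig units and stage fractions", {
  sf <- tibble::tibble(farm_class = "large_scale", stage = "housing",
                       fraction = 0.3)
  # 1000 pu x 7.2 kg N x 0.3 x 17/14 = 2622.857 kg
  e <- livestock_emissions(1000, "large_scale", 7.2, sf)
  expect_equal(unname(e), 1000 * 7.2 * 0.3 * 17 / 14, tolerance = 1e-12)
  expect_equal(unname(livestock_emissions(0, "large_scale", 7.2, sf)), 0)
  sf0 <- tibble::tibble(farm_class = "free_range",
                        stage = c("spreading", "grazing"), fraction = 0)
  expect_equal(sum(livestock_emissions(500, "free_range", 7.2, sf0)), 0)
  expect_error(livestock_emissions(10, "industrial", 7.2, sf), "farm_class")
  sf_bad <- tibble::tibble(farm_class = "large_scale",
                           stage = c("housing", "storage"),
                           fraction = c(0.6, 0.6))
  expect_error(livestock_emissions(10, "large_scale", 7.2, sf_bad), "sum")
})

test_that("the total inventory is consistent, non-negative and closed", {
  r <- small_region(seed = 21)
  field <- total_inventory(r)
  expect_true(all(field$emission_gg >= 0))
  expect_setequal(unique(field$sector), emission_sectors())

  # per-cell sector sums equal the cell totals (independent summation oracle)
  cell_tot <- emission_summary(field, "cell")
  manual <- tapply(field$emission_gg, field$cell_id, sum)
  expect_equal(as.numeric(manual[as.character(cell_tot$cell_id)]),
               cell_tot$emission_gg, tolerance = 1e-12)

  # sector shares close to 100%
  sect <- emission_summary(field, "sector")
  expect_equal(sum(100 * sect$emission_tg / sum(sect$emission_tg)), 100,
               tolerance = 1e-6)

  # with all EFs zero the field vanishes
  f0 <- default_emission_factors()
  f0$fertilizer_ef <- 0
  f0$stage_fractions$fraction <- 0
  f0$other_total_gg <- 0
  expect_equal(sum(total_inventory(r, f0)$emission_gg), 0)

  # missing sector parameters are a configuration error
  f_bad <- default_emission_factors()
  f_bad$other_total_gg <- NULL
  expect_error(total_inventory(r, f_bad), "other_total_gg")
})

test_that("scaling all activity scales every emission proportionally", {
  r <- small_region(seed = 22)
  f <- default_emission_factors()
  base <- total_inventory(r, f)
  r2 <- r
  r2$cells$cropland_ha <- r$cells$cropland_ha * 2
  hcols <- paste0("parcel_ha_", 1:6)
  r2$cells[, hcols] <- r$cells[, hcols] * 2
  for (s in names(pig_unit_factors())) r2$farms[[s]] <- r$farms[[s]] * 2
  f2 <- f
  f2$other_total_gg <- f$other_total_gg * 2
  doubled <- total_inventory(r2, f2)
  expect_equal(doubled$emission_gg, 2 * base$emission_gg, tolerance = 1e-12)
})

test_that("warm-season emissions exceed cold-season emissions", {
  field <- total_inventory(small_region(seed = 23))
  mon <- emission_summary(field, "month")
  summer <- sum(mon$emission_tg[mon$month %in% 6:8])
  winter <- sum(mon$emission_tg[mon$month %in% c(12, 1, 2)])
  expect_gt(summer, winter)
})

test_that("Monte Carlo CI collapses without uncertainty and is seeded", {
  r <- small_region(seed = 24)
  f <- default_emission_factors()
  f$uncertainty_gsd <- c(fertilizer = 1, livestock = 1, other = 1)
  mc <- monte_carlo_ci(r, f, n_draws = 200, seed = 5)
  expect_equal(mc$p05, mc$mean, tolerance = 1e-12)
  expect_equal(mc$p95, mc$mean, tolerance = 1e-12)

  f2 <- default_emission_factors()
  mc1 <- monte_carlo_ci(r, f2, n_draws = 500, seed = 9)
  mc2 <- monte_carlo_ci(r, f2, n_draws = 500, seed = 9)
  expect_identical(mc1, mc2)
  expect_lte(mc1$p05, mc1$mean)
  expect_lte(mc1$mean, mc1$p95)
  expect_error(monte_carlo_ci(r, f2, n_draws = 1), "n_draws")
})

test_that("Monte Carlo percentiles match analytic log-normal quantiles", {
  # single-factor toy inventory: fertilizer only, GSD 1.2
  lv <- region_config()$livestock
  lv$total_pig_units <- 1
  r <- small_region(seed = 25, livestock = lv)
  f <- default_emission_factors()
  f$stage_fractions$fraction <- 0
  f$other_total_gg <- 0
  f$uncertainty_gsd <- c(fertilizer = 1.2, livestock = 1, other = 1)
  base_tg <- emission_summary(total_inventory(r, f))
  mc <- monte_carlo_ci(r, f, n_draws = 10000, seed = 31)
  expect_equal(mc$p05, base_tg * qlnorm(0.05, 0, log(1.2)), tolerance = 0.01)
  expect_equal(mc$p95, base_tg * qlnorm(0.95, 0, log(1.2)), tolerance = 0.01)
})
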