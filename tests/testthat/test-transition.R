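test_that("pig-unit conversion uses the species factors", {
  expect_equal(pig_units(c(dairy_cattle = 10)), 100)
  expect_equal(pig_units(c(broiler_poultry = 60, sheep_goats = 3)), 2)
  expect_equal(pig_units(c()), 0)
  expect_equal(pig_units(c(swine = 7)), 7)
  expect_error(pig_units(c(llama = 3)), "unknown species")
  expect_error(pig_units(c(swine = -1)), "heads")
})

test_that("consolidation merges sub-threshold mass only on gentle terrain", {
  bins <- c(0, 0.5, 1, 2, 5, 10, 50)
  h <- c(0, 0, 100, 50, 0, 0)   # 100 ha in 1-2 ha bin, 50 ha in 2-5 ha bin
  expect_identical(consolidate_parcels(h, slope = 10, bins), h)
  out <- consolidate_parcels(h, slope = 2, bins)
  expect_equal(out, c(0, 0, 0, 150, 0, 0))
  expect_equal(large_scale_fraction(out, bins), 1)
  expect_error(consolidate_parcels(h, slope = -1, bins), "slope")
})

test_that("consolidation conserves cropland on random histograms", {
  set.seed(101)
  for (i in 1:1000) {
    h <- random_histogram()
    s <- runif(1, 0, 12)
    out <- consolidate_parcels(h, s)
    expect_identical(sum(out), sum(h))
  }
})

test_that("N rate responds to mean parcel size with the power law", {
  bins <- c(0, 0.5, 1, 2, 5, 10, 50)
  h <- c(10, 20, 30, 10, 5, 1)
  expect_equal(n_rate_after(150, h, h, bins, -0.3), 150)
  expect_equal(n_rate_after(150, h, h, bins, 0), 150)
  # a 4-fold size ratio at elasticity -0.27 multiplies the rate by 0.688
  bins4 <- c(0, 1, 2, 4, 8, 16, 32)
  h1 <- c(0, 100, 0, 0, 0, 0)   # mean 1.5 ha
  h4 <- c(0, 0, 0, 100, 0, 0)   # mean 6 ha: ratio 4
  expect_equal(n_rate_after(100, h1, h4, bins4, -0.27), 100 * 4^-0.27,
               tolerance = 1e-12)
  expect_equal(100 * 4^-0.27, 68.8, tolerance = 1e-3)
  # floored at the agronomic minimum
  expect_equal(n_rate_after(60, h1, h4, bins4, -2, floor = 50), 50)
  expect_error(n_rate_after(100, h1, h4, bins4, 0.5), "elasticity")
  expect_error(parcel_mean_size(rep(0, 6), bins), "zero cropland")
})

test_that("reallocation splits free-range units proportionally to capacity", {
  farms <- tibble::tibble(
    farm_id = 1:3, cell_id = c(1L, 1L, 2L),
    farm_class = c("free_range", "large_scale", "large_scale"),
    swine = c(1000, 300, 100))
  pmap <- tibble::tibble(cell_id = 1:2, province_id = c(1L, 1L))
  out <- reallocate_livestock(farms, pmap)
  expect_equal(out$swine, c(0, 300 + 750, 100 + 250))
  # no free-range units: nothing moves
  f2 <- farms[farms$farm_class == "large_scale", ]
  expect_identical(reallocate_livestock(f2, pmap), f2)
})

test_that("reallocation conserves pig units per province", {
  set.seed(77)
  for (i in 1:50) {
    n_prov <- 5
    n_farms <- sample(5:20, 1)
    farms <- tibble::tibble(
      farm_id = seq_len(n_farms),
      cell_id = sample.int(n_prov * 3, n_farms, replace = TRUE),
      farm_class = sample(c("free_range", "large_scale"), n_farms,
                          replace = TRUE),
      swine = runif(n_farms, 0, 5000),
      dairy_cattle = runif(n_farms, 0, 200))
    pmap <- tibble::tibble(cell_id = seq_len(n_prov * 3),
                           province_id = rep(seq_len(n_prov), each = 3))
    keep <- runif(1, 0, 0.3)
    out <- reallocate_livestock(farms, pmap, keep_fraction = keep)
    pv_in <- pmap$province_id[match(farms$cell_id, pmap$cell_id)]
    pv_out <- pmap$province_id[match(out$cell_id, pmap$cell_id)]
    before <- tapply(farms_pig_units(farms), pv_in, sum)
    after <- tapply(farms_pig_units(out), pv_out, sum)
    expect_equal(as.numeric(after[names(before)]), as.numeric(before),
                 tolerance = 1e-12)
  }
})

test_that("a province without large farms gets one new point source", {
  farms <- tibble::tibble(farm_id = 1:2, cell_id = c(1L, 2L),
                          farm_class = "free_range",
                          swine = c(800, 200))
  pmap <- tibble::tibble(cell_id = 1:2, province_id = 1L)
  out <- reallocate_livestock(farms, pmap)
  expect_equal(sum(out$farm_class == "large_scale"), 1)
  expect_equal(out$cell_id[out$farm_class == "large_scale"], 1L)  # biggest pool
  expect_equal(sum(out$swine), 1000)
  expect_error(reallocate_livestock(farms, pmap, allow_new = FALSE),
               "no large-scale farm")
  expect_error(reallocate_livestock(farms, pmap[1, ]), "province")
})

test_that("the full transition conserves mass and is monotone", {
  r <- small_region(seed = 31)
  tr <- apply_transition(r, "all")
  hcols <- paste0("parcel_ha_", 1:6)
  expect_equal(sum(as.matrix(tr$cells[, hcols])),
               sum(as.matrix(r$cells[, hcols])), tolerance = 1e-9)
  expect_equal(sum(tr$cells$cropland_ha), sum(r$cells$cropland_ha))
  # large-scale fraction never decreases; N rate never increases
  bins <- r$config$parcel_size_bins
  for (i in seq_len(nrow(r$cells))) {
    f0 <- large_scale_fraction(as.numeric(r$cells[i, hcols]), bins)
    f1 <- large_scale_fraction(as.numeric(tr$cells[i, hcols]), bins)
    expect_gte(f1, f0)
  }
  expect_true(all(tr$cells$n_rate <= r$cells$n_rate + 1e-12))
  expect_equal(sum(farms_pig_units(tr$farms)),
               sum(farms_pig_units(r$farms)), tolerance = 1e-6)

  # pilot regime leaves non-pilot provinces untouched
  trp <- apply_transition(r, "pilot")
  non_pilot <- !r$cells$is_pilot
  expect_equal(trp$cells$n_rate[non_pilot], r$cells$n_rate[non_pilot])
})

test_that("the default region's N-rate decline matches the calibration", {
  r <- default_region_cached()
  tr <- apply_transition(r, "all")
  s <- attr(tr, "transition_summary")
  decline <- 100 * (1 - s$mean_n_rate_after / s$mean_n_rate_before)
  expect_lt(abs(decline - 31.07), 2)
  # large-scale livestock share reaches the configured post-transition level
  expect_equal(s$large_livestock_share_after, 0.928, tolerance = 0.01)
})
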