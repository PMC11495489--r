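test_that("region generation is deterministic and hits configured totals", {
  cfg <- small_config(seed = 3)
  r1 <- generate_region(cfg)
  r2 <- generate_region(cfg)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$farms, r2$farms)

  # conservation of national totals (exact by construction, 0.1% budget)
  expect_equal(sum(r1$cells$cropland_ha), cfg$cropland_total,
               tolerance = 1e-3)
  expect_equal(sum(r1$cells$population), cfg$population_total,
               tolerance = 1e-3)
  expect_equal(sum(farms_pig_units(r1$farms)),
               cfg$livestock$total_pig_units, tolerance = 1e-3)
  # cropland-weighted mean N rate pinned to the target
  expect_equal(
    sum(r1$cells$n_rate * r1$cells$cropland_ha) / sum(r1$cells$cropland_ha),
    cfg$mean_n_rate, tolerance = 1e-6)
})

test_that("parcel histogram mass matches cell cropland", {
  r <- small_region(seed = 5)
  h <- as.matrix(r$cells[, paste0("parcel_ha_", 1:6)])
  expect_equal(rowSums(h), r$cells$cropland_ha, tolerance = 1e-8)
})

test_that("slope field reproduces the configured cropland exceedance share", {
  r <- generate_region(region_config(seed = 42, daily_met = FALSE))
  frac <- with(r$cells, sum(cropland_ha[slope_deg > 6]) / sum(cropland_ha))
  expect_lt(abs(frac - 0.227), 0.02)
})

test_that("free_range_fraction = 0 produces no free-range farms", {
  lv <- region_config()$livestock
  lv$free_range_fraction <- 0
  r <- small_region(seed = 2, livestock = lv)
  expect_false(any(r$farms$farm_class == "free_range"))
  expect_equal(sum(farms_pig_units(r$farms)), lv$total_pig_units,
               tolerance = 1e-6)
})

test_that("pilot provinces carry the majority of activity", {
  r <- small_region(seed = 7)
  pilot_crop <- with(r$cells, sum(cropland_ha[is_pilot]) / sum(cropland_ha))
  pilot_area <- mean(r$cells$is_pilot)
  expect_gt(pilot_crop, pilot_area)  # concentrated well above area share
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(region_config(cell_area = -1), "cell_area")
  expect_error(region_config(pilot_provinces = 99), "pilot_provinces")
  expect_error(region_config(cropland_fraction_range = c(0.5, 2)),
               "cropland_fraction_range")
  lv <- region_config()$livestock
  lv$free_range_fraction <- 1.5
  expect_error(region_config(livestock = lv), "free_range_fraction")
  expect_error(region_config(parcel_size_bins = c(0, 1, 5, 50)),
               "parcel_size_bins")
})

test_that("fixtures round-trip through disk within float tolerance", {
  r <- small_region(seed = 9)
  dir <- withr::local_tempdir()
  write_fixture(r, dir)
  r2 <- read_fixture(dir)
  num <- vapply(r$cells, is.numeric, logical(1))
  for (cn in names(r$cells)[num]) {
    expect_equal(r2$cells[[cn]], r$cells[[cn]], tolerance = 1e-9, info = cn)
  }
  for (cn in intersect(names(r$farms), names(pig_unit_factors()))) {
    expect_equal(r2$farms[[cn]], r$farms[[cn]], tolerance = 1e-9, info = cn)
  }
  expect_equal(r2$monthly_met$temp_c, r$monthly_met$temp_c, tolerance = 1e-9)

  # NetCDF field file carries the named dims, month of length 12
  nc <- ncdf4::nc_open(file.path(dir, "fields.nc"))
  on.exit(ncdf4::nc_close(nc))
  expect_setequal(names(nc$dim), c("row", "col", "month"))
  expect_equal(nc$dim$month$len, 12)
  crop <- ncdf4::ncvar_get(nc, "cropland")
  expect_equal(sum(crop), sum(r$cells$cropland_ha), tolerance = 1e-9)
})

test_that("an empty region writes and reads as a valid empty fixture", {
  r <- generate_region(region_config(n_rows = 0, n_cols = 0, daily_met = FALSE))
  expect_equal(nrow(r$cells), 0)
  dir <- withr::local_tempdir()
  write_fixture(r, dir)
  r2 <- read_fixture(dir)
  expect_equal(nrow(r2$cells), 0)
  expect_equal(nrow(r2$farms), 0)
})

test_that("identical config and seed give byte-identical fixture files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(small_region(seed = 4), d1)
  write_fixture(small_region(seed = 4), d2)
  for (f in c("cells.csv", "farms.csv", "monthly_met.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
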