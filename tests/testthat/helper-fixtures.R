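# Small region used across module tests (fast to generate); the full default
# region is built once per session for the calibration/acceptance checks.
small_config <- function(seed = 11, ...) {
  # an 8 x 8 region with the default per-cell densities: national totals are
  # scaled to the grid's share of the default 30 x 30 region
  f <- 64 / 900
  lv <- region_config()$livestock
  lv$total_pig_units <- lv$total_pig_units * f
  args <- list(n_rows = 8, n_cols = 8, n_provinces = 4,
               pilot_provinces = 1L, daily_met = FALSE, seed = seed,
               cropland_total = 134.9e6 * f,
               population_total = 1.39e9 * f,
               livestock = lv)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(region_config, args)
}

small_region <- function(seed = 11, ...) generate_region(small_config(seed, ...))

.fixture_cache <- new.env(parent = emptyenv())

default_region_cached <- function() {
  if (is.null(.fixture_cache$region)) {
    .fixture_cache$region <- generate_region(region_config(seed = 42))
  }
  .fixture_cache$region
}

default_field_cached <- function() {
  if (is.null(.fixture_cache$field)) {
    .fixture_cache$field <- total_inventory(default_region_cached())
  }
  .fixture_cache$field
}

# random parcel histogram (mass per bin) for property tests
random_histogram <- function(bins = c(0, 0.5, 1, 2, 5, 10, 50)) {
  m <- runif(length(bins) - 1, 0, 100)
  m[sample.int(length(m), sample.int(3, 1))] <- 0
  m
}
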