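#' Configure a synthetic study region
#'
#' Builds the configuration object for [generate_region()]. The defaults
#' describe a China-like desk-scale region: a 30 x 30 grid of 1 Mha cells
#' (9 Mkm2 total), 134.9 Mha of cropland at a mean N application rate of
#' 197.8 kg N/ha, 1.6 billion pig units of livestock of which 62.5% are
#' free-range, 22.7% of cropland on slopes above 6 degrees, 80.8% of cropland
#' mass in parcels under 2 ha, and a block of pilot provinces covering ~20%
#' of the area that carries the majority of agricultural activity.
#'
#' @param n_rows,n_cols Grid dimensions (cell (0,0) is the north-west corner).
#' @param cell_area Cell area in ha.
#' @param n_provinces Number of provinces (contiguous rectangular blocks).
#' @param pilot_provinces Integer ids of pilot provinces (subset of
#'   `1:n_provinces`).
#' @param pilot_intensity Latent-field boost applied inside pilot provinces;
#'   controls how strongly activity concentrates there.
#' @param cropland_fraction_range Admissible per-cell cropland fraction.
#' @param cropland_total Total cropland, ha.
#' @param slope_distribution List: `sdlog` of the log-normal slope field,
#'   `exceed_target` (cropland fraction steeper than `exceed_threshold`) and
#'   `exceed_threshold` (degrees).
#' @param parcel_size_bins Parcel-size bin edges, ha. The 2-ha large-scale
#'   threshold must be one of the edges.
#' @param parcel_sdlog Log-normal sigma of within-cell parcel sizes.
#' @param sub2ha_mass_share National share of cropland mass in parcels below
#'   2 ha (the generator is calibrated to reproduce it).
#' @param mean_n_rate National cropland-weighted mean N rate, kg N/ha.
#' @param livestock List: `total_pig_units`, `free_range_fraction`,
#'   `species_share` (named, sums to 1, in pig-unit terms),
#'   `typical_farm_pu` (mean large-farm size, pig units).
#' @param population_total Persons.
#' @param baseline_mortality Named deaths/person/yr per cause.
#' @param met_params List: `t_mean`, `t_seasonal_amplitude`,
#'   `t_latitude_range` (degrees C), `rh_mean`, `rh_seasonal_amplitude`,
#'   `daily_rho`, `daily_sd` (AR(1) daily log-deviations).
#' @param daily_met Generate the per-cell daily series needed for
#'   polluted-day counting?
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `nh3_region_config`.
#' @export
#' @examples
#' cfg <- region_config(n_rows = 6, n_cols = 6, seed = 1)
region_config <- function(n_rows = 30, n_cols = 30,
                          cell_area = 1e6,
                          n_provinces = 30,
                          pilot_provinces = c(9, 10, 11, 15, 16, 17),
                          pilot_intensity = 2.5,
                          cropland_fraction_range = c(0, 0.85),
                          cropland_total = 134.9e6,
                          slope_distribution = list(sdlog = 1.0,
                                                    exceed_target = 0.227,
                                                    exceed_threshold = 6),
                          parcel_size_bins = c(0, 0.5, 1, 2, 5, 10, 50),
                          parcel_sdlog = 1.1,
                          sub2ha_mass_share = 0.808,
                          mean_n_rate = 197.8,
                          livestock = list(
                            total_pig_units = 1.6e9,
                            free_range_fraction = 0.625,
                            species_share = c(swine = 0.45, dairy_cattle = 0.06,
                                              beef_cattle = 0.10,
                                              sheep_goats = 0.15,
                                              layer_poultry = 0.12,
                                              broiler_poultry = 0.12),
                            typical_farm_pu = 1e5
                          ),
                          population_total = 1.39e9,
                          baseline_mortality = c(copd = 6.5e-4,
                                                 lung_cancer = 4.5e-4,
                                                 ihd = 1.2e-3,
                                                 stroke = 1.5e-3),
                          met_params = list(t_mean = 14,
                                            t_seasonal_amplitude = 12,
                                            t_latitude_range = 10,
                                            rh_mean = 0.65,
                                            rh_seasonal_amplitude = 0.10,
                                            daily_rho = 0.8,
                                            daily_sd = 0.25),
                          daily_met = TRUE,
                          seed = 42) {
  cfg <- list(
    n_rows = n_rows, n_cols = n_cols, cell_area = cell_area,
    n_provinces = n_provinces, pilot_provinces = pilot_provinces,
    pilot_intensity = pilot_intensity,
    cropland_fraction_range = cropland_fraction_range,
    cropland_total = cropland_total,
    slope_distribution = slope_distribution,
    parcel_size_bins = parcel_size_bins, parcel_sdlog = parcel_sdlog,
    sub2ha_mass_share = sub2ha_mass_share,
    mean_n_rate = mean_n_rate, livestock = livestock,
    population_total = population_total,
    baseline_mortality = baseline_mortality,
    met_params = met_params, daily_met = daily_met, seed = seed
  )
  validate_region_config(cfg)
  structure(cfg, class = "nh3_region_config")
}

validate_region_config <- function(cfg) {
  if (!is.numeric(cfg$n_rows) || cfg$n_rows < 0 || cfg$n_rows != round(cfg$n_rows))
    abort_config("n_rows", "must be a non-negative integer")
  if (!is.numeric(cfg$n_cols) || cfg$n_cols < 0 || cfg$n_cols != round(cfg$n_cols))
    abort_config("n_cols", "must be a non-negative integer")
  if (!is.numeric(cfg$cell_area) || cfg$cell_area <= 0)
    abort_config("cell_area", "must be > 0")
  if (length(cfg$pilot_provinces) &&
      (any(cfg$pilot_provinces < 1) || any(cfg$pilot_provinces > cfg$n_provinces)))
    abort_config("pilot_provinces", "must be a subset of 1:n_provinces")
  r <- cfg$cropland_fraction_range
  if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2])
    abort_config("cropland_fraction_range", "must be an ordered interval in [0, 1]")
  fr <- cfg$livestock$free_range_fraction
  if (fr < 0 || fr > 1)
    abort_config("livestock$free_range_fraction", "must lie in [0, 1]")
  ss <- cfg$livestock$species_share
  if (abs(sum(ss) - 1) > 1e-8 || any(ss < 0))
    abort_config("livestock$species_share", "must be non-negative and sum to 1")
  if (!any(abs(cfg$parcel_size_bins - 2) < 1e-12))
    abort_config("parcel_size_bins", "must include the 2 ha large-scale threshold as an edge")
  if (any(cfg$baseline_mortality < 0))
    abort_config("baseline_mortality", "rates must be >= 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    abort_config("seed", "must be a single integer")
  invisible(cfg)
}

# parcel-size mass CDF: fraction of cropland mass in parcels below `x` for a
# log-normal size distribution truncated to the bin range (mass-weighted CDF
# of LN(mu, sigma) is a normal CDF shifted by sigma^2)
parcel_mass_cdf <- function(x, mu, sigma, lo, hi) {
  num <- pnorm((log(x) - mu - sigma^2) / sigma) -
    pnorm((log(lo) - mu - sigma^2) / sigma)
  den <- pnorm((log(hi) - mu - sigma^2) / sigma) -
    pnorm((log(lo) - mu - sigma^2) / sigma)
  pmin(1, pmax(0, num / den))
}

#' Generate a synthetic study region
#'
#' Draws a seeded, self-consistent region fixture: gridded cropland with
#' spatially autocorrelated hotspot structure concentrated in the pilot
#' provinces, terrain slope quantile-mapped so a configurable share of
#' cropland exceeds 6 degrees, per-cell parcel-size histograms calibrated to
#' the national sub-2-ha mass share, N application rates, population,
#' cause-specific mortality rates, livestock point sources split into
#' free-range and large-scale farm classes, and monthly (plus optional
#' daily) meteorology.
#'
#' National totals (cropland, pig units, population) match the configured
#' targets exactly by construction; identical `(config, seed)` give
#' identical fixtures.
#'
#' @param config A [region_config()] object.
#' @return A list of class `nh3_region` with tibbles `cells`, `farms`,
#'   `monthly_met`, `daily_met` (or `NULL`) and the `config`.
#' @export
#' @examples
#' reg <- generate_region(region_config(n_rows = 6, n_cols = 6, seed = 1,
#'                                      daily_met = FALSE))
#' nrow(reg$cells)
generate_region <- function(config) {
  validate_region_config(config)
  set.seed(substream_seed(config$seed, "region"))
  nr <- config$n_rows; nc <- config$n_cols
  n <- nr * nc
  if (n == 0) {
    return(empty_region(config))
  }
  row <- rep(0:(nr - 1), each = nc)
  col <- rep(0:(nc - 1), times = nr)
  cell_id <- seq_len(n)

  # provinces as rectangular blocks
  npr <- max(1, floor(sqrt(config$n_provinces)))
  npc <- ceiling(config$n_provinces / npr)
  band_r <- pmin(npr - 1, floor(row / nr * npr))
  band_c <- pmin(npc - 1, floor(col / nc * npc))
  province_id <- pmin(config$n_provinces, band_r * npc + band_c + 1)
  is_pilot <- province_id %in% config$pilot_provinces

  # latent autocorrelated fields; pilot provinces get a hotspot boost
  boost <- config$pilot_intensity * is_pilot
  z_crop <- smooth_field(nr, nc) + boost
  z_liv <- 0.7 * z_crop + 0.3 * smooth_field(nr, nc) + 0.3 * boost
  z_pop <- 0.6 * z_crop + 0.4 * smooth_field(nr, nc) + 0.3 * boost
  z_slope <- smooth_field(nr, nc)
  z_parcel <- smooth_field(nr, nc)
  z_nrate <- 0.5 * z_crop + 0.5 * smooth_field(nr, nc)

  # cropland: logistic transform, rescaled to the national total, capped
  cap <- config$cropland_fraction_range[2] * config$cell_area
  if (config$cropland_total > 0.95 * n * cap) {
    abort_config("cropland_total",
                 "exceeds the region's cropland capacity (cells x cell_area x max fraction)")
  }
  frac_raw <- plogis(-1.8 + 1.1 * z_crop)
  cropland <- frac_raw * config$cell_area
  cropland <- cropland * config$cropland_total / sum(cropland)
  for (i in 1:5) {  # cap and redistribute the clipped mass
    over <- pmax(0, cropland - cap)
    if (sum(over) == 0) break
    cropland <- pmin(cropland, cap)
    free <- pmax(0, cap - cropland)
    cropland <- cropland + sum(over) * free / sum(free)
  }
  cropland <- pmin(cropland, cap)
  cropland <- cropland * config$cropland_total / sum(cropland)

  # slope: weighted quantile mapping so the cropland-weighted exceedance of
  # the threshold matches the configured target
  sd_ <- config$slope_distribution
  meanlog <- log(sd_$exceed_threshold) - qnorm(1 - sd_$exceed_target) * sd_$sdlog
  ord <- order(z_slope)
  w <- cropland[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  slope <- numeric(n)
  slope[ord] <- qlnorm(p, meanlog, sd_$sdlog)

  # parcel histograms: per-cell log-normal mu with spatial variation, with a
  # global shift calibrated so the national sub-2-ha mass share is exact
  bins <- config$parcel_size_bins
  sigma <- config$parcel_sdlog
  lo <- max(min(bins), 1e-3); hi <- max(bins)
  mu_cell <- -1.47 + 0.25 * z_parcel
  target <- config$sub2ha_mass_share
  f_share <- function(delta) {
    sub2 <- parcel_mass_cdf(2, mu_cell + delta, sigma, lo, hi)
    sum(cropland * sub2) / sum(cropland) - target
  }
  delta <- tryCatch(stats::uniroot(f_share, c(-4, 4))$root, error = function(e) 0)
  mu_cell <- mu_cell + delta
  nb <- length(bins) - 1
  hist_mat <- matrix(0, n, nb)
  cdf_prev <- parcel_mass_cdf(pmax(bins[1], lo), mu_cell, sigma, lo, hi)
  for (b in seq_len(nb)) {
    cdf_b <- parcel_mass_cdf(bins[b + 1], mu_cell, sigma, lo, hi)
    hist_mat[, b] <- (cdf_b - cdf_prev) * cropland
    cdf_prev <- cdf_b
  }
  # normalize tiny truncation residue so rows sum exactly to cropland
  rs <- rowSums(hist_mat)
  hist_mat[rs > 0, ] <- hist_mat[rs > 0, ] * cropland[rs > 0] / rs[rs > 0]

  # N application rate, cropland-weighted mean pinned to the target
  nr_raw <- exp(0.25 * z_nrate)
  n_rate <- nr_raw * config$mean_n_rate * sum(cropland) / sum(nr_raw * cropland)

  # population
  pshare <- exp(1.0 * z_pop)
  population <- pshare / sum(pshare) * config$population_total

  # mortality rates with mild spatial jitter around the national rates
  mort <- sapply(config$baseline_mortality, function(m0) {
    m0 * exp(0.1 * rnorm(n))
  })
  colnames(mort) <- paste0("mort_", names(config$baseline_mortality))

  cells <- tibble::tibble(
    cell_id = cell_id, row = row, col = col,
    province_id = province_id, is_pilot = is_pilot,
    area_ha = config$cell_area, cropland_ha = cropland,
    slope_deg = slope, n_rate = n_rate, population = population
  )
  cells <- dplyr::bind_cols(cells, tibble::as_tibble(mort))
  hist_df <- tibble::as_tibble(hist_mat, .name_repair = "minimal")
  names(hist_df) <- paste0("parcel_ha_", seq_len(nb))
  cells <- dplyr::bind_cols(cells, hist_df)

  farms <- generate_farms(cells, z_liv, config)
  monthly_met <- generate_monthly_met(cells, config)
  daily_met <- if (isTRUE(config$daily_met)) generate_daily_met(cells, config) else NULL

  structure(list(cells = cells, farms = farms, monthly_met = monthly_met,
                 daily_met = daily_met, config = config),
            class = "nh3_region")
}

empty_region <- function(config) {
  structure(list(
    cells = tibble::tibble(cell_id = integer(), row = integer(),
                           col = integer(), province_id = integer(),
                           is_pilot = logical(), area_ha = numeric(),
                           cropland_ha = numeric(), slope_deg = numeric(),
                           n_rate = numeric(), population = numeric()),
    farms = empty_farms(),
    monthly_met = tibble::tibble(cell_id = integer(), month = integer(),
                                 temp_c = numeric(), rh = numeric()),
    daily_met = NULL, config = config
  ), class = "nh3_region")
}

livestock_species <- c("swine", "dairy_cattle", "beef_cattle", "sheep_goats",
                       "layer_poultry", "broiler_poultry")

empty_farms <- function() {
  out <- tibble::tibble(farm_id = integer(), cell_id = integer(),
                        farm_class = character())
  for (s in livestock_species) out[[s]] <- numeric()
  out
}

generate_farms <- function(cells, z_liv, config) {
  lv <- config$livestock
  n <- nrow(cells)
  share <- exp(1.0 * z_liv)
  pu_cell <- share / sum(share) * lv$total_pig_units
  free_pu <- pu_cell * lv$free_range_fraction
  large_pu <- pu_cell - free_pu
  puf <- pig_unit_factors()
  sp <- lv$species_share

  # one aggregated free-range point per cell
  free <- tibble::tibble(cell_id = cells$cell_id, farm_class = "free_range")
  for (s in names(sp)) free[[s]] <- free_pu * sp[[s]] / puf[[s]]

  # large-scale farms: a few point sources per cell and species, sized with
  # gamma jitter around the typical farm size
  rows <- list()
  for (s in names(sp)) {
    pu_s <- large_pu * sp[[s]]
    n_farms <- pmax(1L, round(pu_s / lv$typical_farm_pu))
    n_farms[pu_s <= 0] <- 0L
    tot_farms <- sum(n_farms)
    if (tot_farms == 0) next
    wts <- rgamma(tot_farms, shape = 4, rate = 4)
    idx <- rep.int(seq_len(n), n_farms)
    wsum <- tapply(wts, idx, sum)
    pu_f <- pu_s[idx] * wts / as.numeric(wsum[as.character(idx)])
    df <- tibble::tibble(cell_id = cells$cell_id[idx], farm_class = "large_scale")
    for (s2 in names(sp)) df[[s2]] <- 0
    df[[s]] <- pu_f / puf[[s]]
    rows[[s]] <- df
  }
  large <- dplyr::bind_rows(rows)
  farms <- dplyr::bind_rows(free[free_pu > 0, , drop = FALSE], large)
  if (nrow(farms) == 0) return(empty_farms())
  farms <- farms[order(farms$cell_id, farms$farm_class), ]
  farms$farm_id <- seq_len(nrow(farms))
  farms[, c("farm_id", "cell_id", "farm_class", livestock_species)]
}

generate_monthly_met <- function(cells, config) {
  mp <- config$met_params
  n <- nrow(cells)
  months <- 1:12
  lat_frac <- if (max(cells$row) > 0) cells$row / max(cells$row) else rep(0.5, n)
  t_lat <- (lat_frac - 0.5) * mp$t_latitude_range  # north (row 0) colder
  grid <- expand.grid(cell_id = cells$cell_id, month = months)
  seas <- mp$t_seasonal_amplitude * cos(2 * pi * (grid$month - 7) / 12)
  temp <- mp$t_mean + t_lat[grid$cell_id] + seas + rnorm(nrow(grid), 0, 0.5)
  rh <- mp$rh_mean + mp$rh_seasonal_amplitude * cos(2 * pi * (grid$month - 7) / 12) +
    rnorm(nrow(grid), 0, 0.02)
  tibble::tibble(cell_id = grid$cell_id, month = grid$month,
                 temp_c = temp, rh = pmin(0.98, pmax(0.2, rh)))
}

generate_daily_met <- function(cells, config) {
  mp <- config$met_params
  n <- nrow(cells)
  n_days <- 365
  innov <- matrix(rnorm(n_days * n, 0, mp$daily_sd), n_days, n)
  z <- apply(innov, 2, function(e) {
    as.numeric(stats::filter(e, mp$daily_rho, method = "recursive"))
  })
  tibble::tibble(
    cell_id = rep(cells$cell_id, each = n_days),
    day = rep(seq_len(n_days), times = n),
    z = as.vector(z)
  )
}

#' @export
print.nh3_region <- function(x, ...) {
  cat("<nh3_region> ", x$config$n_rows, "x", x$config$n_cols, " cells, ",
      nrow(x$farms), " farm points\n", sep = "")
  cat("  cropland: ", format(sum(x$cells$cropland_ha) / 1e6, digits = 4),
      " Mha; population: ",
      format(sum(x$cells$population) / 1e9, digits = 3), " bn\n", sep = "")
  invisible(x)
}
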