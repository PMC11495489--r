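#' Sector names of an emission field
#'
#' The fixed, closed sector list of the inventory: fertilizer application,
#' the four livestock manure stages, and an aggregate non-agricultural
#' remainder.
#' @export
emission_sectors <- function() {
  c("fertilizer", "livestock_housing", "livestock_storage",
    "livestock_spreading", "livestock_grazing", "other")
}

# temperature-modulated monthly allocation: base weights scaled by
# exp(s * T_m), renormalized. s > 0 shifts emission toward warm months.
monthly_allocation <- function(weights, temp_c, sensitivity) {
  if (abs(sum(weights) - 1) > 1e-8) {
    abort_domain("`monthly_weights` must sum to 1")
  }
  w <- weights * exp(sensitivity * temp_c)
  w / sum(w)
}

#' Fertilizer NH3 emissions for one cell
#'
#' Annual emission is `n_rate * cropland * ef * 17/14` (kg NH3): the applied
#' nitrogen mass times the volatilized fraction, converted from N to NH3
#' mass. The annual mass is split across months by the base weights modulated
#' by `exp(temperature_sensitivity * T)` and renormalized, so warm months
#' carry more of the annual emission.
#'
#' @param n_rate N application rate, kg N/ha (scalar, >= 0).
#' @param cropland Cropland area, ha.
#' @param ef Volatilization fraction of applied N, in `[0, 1]`.
#' @param monthly_weights Base monthly weights, length 12, summing to 1.
#' @param temp_c Monthly mean temperature series, length 12 (degrees C).
#' @param temperature_sensitivity Dimensionless scaling per degree C.
#' @return Numeric length 12: kg NH3 per month.
#' @export
#' @examples
#' e <- fertilizer_emissions(100, 1000, 0.12, rep(1 / 12, 12), rep(15, 12))
#' sum(e)  # 100 * 1000 * 0.12 * 17/14 = 14571.43 kg
fertilizer_emissions <- function(n_rate, cropland, ef,
                                 monthly_weights = rep(1 / 12, 12),
                                 temp_c = rep(15, 12),
                                 temperature_sensitivity = 0) {
  if (any(n_rate < 0)) abort_domain("`n_rate` must be >= 0")
  check_fraction(ef, "ef")
  check_nonneg(cropland, "cropland")
  annual <- n_rate * cropland * ef * N_TO_NH3
  annual * monthly_allocation(monthly_weights, temp_c, temperature_sensitivity)
}

#' Livestock NH3 emissions by manure stage
#'
#' Per-stage annual emission is
#' `pig_units * excretion_n * stage_fraction * 17/14` (kg NH3). Free-range
#' animals have no housing or storage stages; their excreted N reaches the
#' spreading and grazing stages directly. The per-class stage fractions must
#' sum to at most 1, so total emitted NH3-N never exceeds excreted N.
#'
#' @param pig_units Pig units (scalar, >= 0).
#' @param farm_class `"free_range"` or `"large_scale"`.
#' @param excretion_n Excreted N, kg N per pig unit per year.
#' @param stage_fractions Tibble with columns `farm_class`, `stage`,
#'   `fraction` (volatilized fraction of excreted N per stage).
#' @return Named numeric: kg NH3 per year per stage.
#' @export
#' @examples
#' sf <- tibble::tibble(farm_class = "large_scale", stage = "housing",
#'                      fraction = 0.3)
#' livestock_emissions(1000, "large_scale", 7.2, sf)  # 2622.857 kg
livestock_emissions <- function(pig_units, farm_class, excretion_n,
                                stage_fractions) {
  check_nonneg(pig_units, "pig_units")
  classes <- unique(stage_fractions$farm_class)
  if (!farm_class %in% classes) {
    abort_domain(sprintf("unknown farm_class `%s`", farm_class))
  }
  sf <- stage_fractions[stage_fractions$farm_class == farm_class, ]
  if (sum(sf$fraction) > 1 + 1e-9) {
    abort_domain("stage fractions must sum to <= 1 per farm class")
  }
  setNames(pig_units * excretion_n * sf$fraction * N_TO_NH3, sf$stage)
}

#' Compute the full gridded seasonal sectoral inventory
#'
#' Assembles the per-(cell, sector, month) NH3 emission field from the
#' fixture and the emission-factor set: fertilizer from N rate and cropland,
#' livestock stages from farm pig units by class, and the non-agricultural
#' remainder distributed proportionally to population with uniform
#' seasonality. Agricultural sectors are allocated to months with the
#' temperature modulation of [fertilizer_emissions()].
#'
#' @param fixture An `nh3_region`.
#' @param factors Emission factors, see [default_emission_factors()].
#' @return Tibble of class `nh3_emission_field` with columns `cell_id`,
#'   `sector`, `month`, `emission_gg` (Gg NH3/month).
#' @export
total_inventory <- function(fixture, factors = default_emission_factors()) {
  stopifnot(inherits(fixture, "nh3_region"))
  req <- c("fertilizer_ef", "excretion_n", "stage_fractions", "other_total_gg")
  miss <- setdiff(req, names(factors))
  if (length(miss)) {
    abort_config(miss[1], "missing sector parameter in emission factors")
  }
  cells <- fixture$cells
  n <- nrow(cells)
  if (n == 0) {
    return(structure(tibble::tibble(cell_id = integer(), sector = character(),
                                    month = integer(), emission_gg = numeric()),
                     class = c("nh3_emission_field", class(tibble::tibble()))))
  }
  met <- fixture$monthly_met
  temp <- matrix(met$temp_c[order(met$cell_id, met$month)], nrow = n,
                 ncol = 12, byrow = TRUE)
  s <- factors$temperature_sensitivity
  w_base <- factors$monthly_weights
  wmat <- exp(s * temp) * rep(w_base, each = n)
  wmat <- wmat / rowSums(wmat)

  # fertilizer, kg/yr per cell
  fert_annual <- cells$n_rate * cells$cropland_ha * factors$fertilizer_ef * N_TO_NH3

  # livestock: pig units per cell and class -> per-stage annual kg
  farms <- fixture$farms
  pu <- farms_pig_units(farms)
  pu_cc <- tapply(pu, list(farms$cell_id, farms$farm_class), sum)
  get_pu <- function(class) {
    v <- rep(0, n)
    if (!is.null(pu_cc) && class %in% colnames(pu_cc)) {
      got <- pu_cc[, class]
      v[as.integer(rownames(pu_cc))] <- ifelse(is.na(got), 0, got)
    }
    v
  }
  pu_free <- get_pu("free_range")
  pu_large <- get_pu("large_scale")
  sf <- factors$stage_fractions
  stage_annual <- list(livestock_housing = 0, livestock_storage = 0,
                       livestock_spreading = 0, livestock_grazing = 0)
  for (stage in c("housing", "storage", "spreading", "grazing")) {
    f_free <- sum(sf$fraction[sf$farm_class == "free_range" & sf$stage == stage])
    f_large <- sum(sf$fraction[sf$farm_class == "large_scale" & sf$stage == stage])
    stage_annual[[paste0("livestock_", stage)]] <-
      (pu_free * f_free + pu_large * f_large) * factors$excretion_n * N_TO_NH3
  }

  # non-agricultural remainder: population-proportional, uniform months
  other_annual <- factors$other_total_gg * 1e6 *
    cells$population / sum(cells$population)

  month_field <- function(annual_kg, weights) {
    # kg/yr -> Gg/month
    sweep_w <- annual_kg * weights
    tibble::tibble(
      cell_id = rep(cells$cell_id, times = 12),
      month = rep(1:12, each = n),
      emission_gg = as.vector(sweep_w) / 1e6
    )
  }
  uniform <- matrix(1 / 12, n, 12)
  parts <- list(
    fertilizer = month_field(fert_annual, wmat),
    livestock_housing = month_field(stage_annual$livestock_housing, wmat),
    livestock_storage = month_field(stage_annual$livestock_storage, wmat),
    livestock_spreading = month_field(stage_annual$livestock_spreading, wmat),
    livestock_grazing = month_field(stage_annual$livestock_grazing, wmat),
    other = month_field(other_annual, uniform)
  )
  field <- dplyr::bind_rows(parts, .id = "sector")
  field <- field[, c("cell_id", "sector", "month", "emission_gg")]
  field <- field[order(field$cell_id, match(field$sector, emission_sectors()),
                       field$month), ]
  structure(field, class = c("nh3_emission_field", class(field)))
}

#' Summaries of an emission field
#'
#' @param field An `nh3_emission_field`.
#' @param by One of `"total"`, `"sector"`, `"month"`, `"cell"`.
#' @return For `"total"`, the national annual total in Tg; otherwise a tibble
#'   of Tg (or Gg for `"cell"`) aggregates.
#' @export
emission_summary <- function(field, by = c("total", "sector", "month", "cell")) {
  by <- match.arg(by)
  switch(by,
    total = sum(field$emission_gg) / 1e3,
    sector = dplyr::summarise(dplyr::group_by(field, .data$sector),
                              emission_tg = sum(.data$emission_gg) / 1e3,
                              .groups = "drop"),
    month = dplyr::summarise(dplyr::group_by(field, .data$month),
                             emission_tg = sum(.data$emission_gg) / 1e3,
                             .groups = "drop"),
    cell = dplyr::summarise(dplyr::group_by(field, .data$cell_id),
                            emission_gg = sum(.data$emission_gg),
                            .groups = "drop")
  )
}

#' Monte Carlo confidence interval for the national total
#'
#' Draws independent log-normal perturbations (median 1, configured
#' geometric SD) for the fertilizer EF, each livestock stage fraction and the
#' non-agricultural total, and returns the empirical 5th/95th percentiles of
#' the perturbed national annual total. Perturbations act multiplicatively on
#' sector totals, so the draws need not re-run the gridded inventory.
#'
#' @param fixture An `nh3_region`.
#' @param factors Emission factors.
#' @param n_draws Number of draws (>= 2; the headline runs use >= 1000).
#' @param seed Integer seed.
#' @return List of class `nh3_mc_result`: `mean`, `p05`, `p95` (Tg/yr),
#'   `n_draws`, `seed`.
#' @export
monte_carlo_ci <- function(fixture, factors = default_emission_factors(),
                           n_draws = 1000, seed = 1) {
  if (n_draws < 2) abort_domain("`n_draws` must be >= 2")
  field <- total_inventory(fixture, factors)
  sect <- emission_summary(field, "sector")
  base <- setNames(sect$emission_tg, sect$sector)
  gsd <- factors$uncertainty_gsd
  set.seed(substream_seed(seed, "monte_carlo"))
  draw_ln <- function(gsd_x, k) {
    if (gsd_x <= 1) matrix(1, n_draws, k) else
      matrix(rlnorm(n_draws * k, 0, log(gsd_x)), n_draws, k)
  }
  liv_sectors <- paste0("livestock_", c("housing", "storage", "spreading", "grazing"))
  liv_base <- base[liv_sectors]
  liv_base[is.na(liv_base)] <- 0
  totals <- as.numeric(
    draw_ln(gsd[["fertilizer"]], 1) * base[["fertilizer"]] +
      draw_ln(gsd[["livestock"]], 4) %*% liv_base +
      draw_ln(gsd[["other"]], 1) * base[["other"]]
  )
  q <- quantile(totals, c(0.05, 0.95), names = FALSE)
  structure(list(mean = mean(totals), p05 = q[1], p95 = q[2],
                 n_draws = n_draws, seed = seed),
            class = "nh3_mc_result")
}

#' @export
print.nh3_mc_result <- function(x, ...) {
  cat(sprintf("<nh3_mc_result> mean %.2f Tg/yr (90%% CI %.2f-%.2f), %d draws\n",
              x$mean, x$p05, x$p95, x$n_draws))
  invisible(x)
}
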