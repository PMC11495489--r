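# molecular weights, g/mol
MW <- c(nh3 = 17.031, hno3 = 63.01, so4 = 96.06, nh4 = 18.039, no3 = 62.004)

# NH4NO3 dissociation constant, ppb^2: ln Kp = a - b/T - c ln(T), with a
# linear deliquescence reduction above the deliquescence RH (particle-phase
# formation is favoured on wet aerosol). Continuous at the deliquescence
# point; floored so Kp stays positive.
kp_nh4no3 <- function(temp_k, rh, airq) {
  ln_kp <- airq$kp_a - airq$kp_b / temp_k - airq$kp_c * log(temp_k)
  kp <- exp(ln_kp)
  drh <- airq$deliquescence_rh
  f <- ifelse(rh > drh, pmax(0.05, 1 - (rh - drh) / (1 - drh)), 1)
  kp * f
}

# ppb -> umol/m3 at 1 atm (ideal gas)
ppb_to_umol <- function(temp_k) 101325 / (8.314 * temp_k) * 1e-3

#' Inorganic aerosol equilibrium
#'
#' Sulfate-first neutralization with temperature/RH-dependent ammonium
#' nitrate formation: ammonia first neutralizes sulfate (up to 2 mol NH4 per
#' mol SO4, bisulfate when ammonia is short), and the remaining ammonia and
#' nitric acid form particulate NH4NO3 only while their molar product
#' exceeds the dissociation constant `Kp(T, RH)`. Total reduced nitrogen and
#' total nitrate are conserved exactly; the response of particulate mass to
#' total ammonia is continuous and piecewise smooth, flat in the NH3-rich
#' regime and steep once ammonia limits neutralization.
#'
#' @param total_nh3 Total ammonia (gas NH3 + particulate NH4, expressed as
#'   NH3 mass), ug/m3. Vectorized.
#' @param sulfate Non-volatile sulfate (as SO4), ug/m3.
#' @param total_nitrate Total nitrate (gas HNO3 + particulate NO3, expressed
#'   as NO3 mass), ug/m3.
#' @param temp_k Temperature, K (must lie in 230-330).
#' @param rh Relative humidity, fraction.
#' @param airq Air-quality parameter list (see [nh3_params()]`$airq`).
#' @return Tibble (class `nh3_aerosol_state`): `nh3_gas`, `hno3_gas`, `nh4`,
#'   `no3`, `sulfate`, `pm25_inorganic`, all ug/m3.
#' @export
#' @examples
#' equilibrium_pm(10, 8, 12, 280, 0.7)
equilibrium_pm <- function(total_nh3, sulfate, total_nitrate, temp_k, rh,
                           airq = nh3_params()$airq) {
  check_nonneg(total_nh3, "total_nh3")
  check_nonneg(sulfate, "sulfate")
  check_nonneg(total_nitrate, "total_nitrate")
  if (any(temp_k < 230 | temp_k > 330)) {
    abort_domain("`temp_k` outside the physical range 230-330 K")
  }
  A <- total_nh3 / MW[["nh3"]]       # umol/m3 total ammonia
  S <- sulfate / MW[["so4"]]
  N <- total_nitrate / MW[["no3"]]
  nh4_sulf <- pmin(A, 2 * S)
  A2 <- A - nh4_sulf
  conv <- ppb_to_umol(temp_k)
  kp <- kp_nh4no3(temp_k, rh, airq) * conv^2  # (umol/m3)^2
  disc <- (A2 - N)^2 + 4 * kp
  x <- (A2 + N - sqrt(disc)) / 2
  x <- pmax(0, pmin(x, pmin(A2, N)))
  x[A2 * N <= kp] <- 0
  out <- tibble::tibble(
    nh3_gas = (A2 - x) * MW[["nh3"]],
    hno3_gas = (N - x) * MW[["hno3"]],
    nh4 = (nh4_sulf + x) * MW[["nh4"]],
    no3 = x * MW[["no3"]],
    sulfate = sulfate,
    pm25_inorganic = sulfate + (nh4_sulf + x) * MW[["nh4"]] + x * MW[["no3"]]
  )
  class(out) <- c("nh3_aerosol_state", class(out))
  out
}

# Gg/month emitted in one cell -> steady-state local concentration, ug/m3:
# flux (ug m-2 s-1) over an effective ventilation velocity (m/s)
emission_to_conc <- function(emission_gg, month, cell_area_ha, dilution_rate) {
  secs <- month_days[month] * 86400
  flux <- emission_gg * 1e15 / (cell_area_ha * 1e4) / secs
  flux / dilution_rate
}

# per-cell, per-month pollution co-factors held fixed across scenarios:
# sulfate, total nitrate and non-inorganic PM scale with a population-based
# pollution weight (mean 1)
pollution_weight <- function(cells) {
  w <- cells$population / mean(cells$population)
  0.5 + 0.5 * w  # softened toward 1; mean stays exactly 1
}

#' Reduced-form PM2.5 response to an emission change
#'
#' One-box steady state per cell and month: the local NH3 concentration is
#' the cell's emission flux divided by an effective ventilation velocity,
#' plus a background term proportional to the regional mean; the result
#' feeds the inorganic aerosol equilibrium against fixed sulfate / total
#' nitrate / non-inorganic PM fields (scaled to a population-based pollution
#' weight). The PM2.5 change is baseline minus scenario.
#'
#' @param baseline,scenario `nh3_emission_field`s on the same grid.
#' @param fixture The `nh3_region` both fields were computed from.
#' @param params Parameter list from [nh3_params()].
#' @return List of class `nh3_pm_response`: `by_cell_month` (tibble with
#'   `pm_base`, `pm_scen`, `d_pm`), `annual` (per-cell annual means),
#'   `summary` (area- and population-weighted national means and percentage
#'   reductions).
#' @export
pm_response <- function(baseline, scenario, fixture, params = nh3_params()) {
  if (nrow(baseline) != nrow(scenario)) {
    abort_domain("baseline and scenario fields are on different grids")
  }
  airq <- params$airq
  cells <- fixture$cells
  met <- fixture$monthly_met

  tot_b <- dplyr::summarise(
    dplyr::group_by(baseline, .data$cell_id, .data$month),
    e = sum(.data$emission_gg), .groups = "drop")
  tot_s <- dplyr::summarise(
    dplyr::group_by(scenario, .data$cell_id, .data$month),
    e = sum(.data$emission_gg), .groups = "drop")
  grid <- dplyr::left_join(tot_b, tot_s, by = c("cell_id", "month"),
                           suffix = c("_base", "_scen"))
  grid <- dplyr::left_join(grid, met, by = c("cell_id", "month"))
  idx <- match(grid$cell_id, cells$cell_id)
  area <- cells$area_ha[idx]
  pw <- pollution_weight(cells)[idx]

  conc_of <- function(e) {
    local <- emission_to_conc(e, grid$month, area, airq$dilution_rate)
    reg <- tapply(local, grid$month, mean)[as.character(grid$month)]
    local + airq$background_mixing * as.numeric(reg)
  }
  nh3_b <- conc_of(grid$e_base)
  nh3_s <- conc_of(grid$e_scen)
  sulf <- airq$sulfate_base * pw
  nitr <- airq$nitrate_base * pw
  other <- airq$pm_other_base * pw
  tk <- grid$temp_c + 273.15
  eq_b <- equilibrium_pm(nh3_b, sulf, nitr, tk, grid$rh, airq)
  eq_s <- equilibrium_pm(nh3_s, sulf, nitr, tk, grid$rh, airq)
  by_cm <- tibble::tibble(
    cell_id = grid$cell_id, month = grid$month,
    nh3_base = nh3_b, nh3_scen = nh3_s,
    pm_base = eq_b$pm25_inorganic + other,
    pm_scen = eq_s$pm25_inorganic + other
  )
  by_cm$d_pm <- by_cm$pm_base - by_cm$pm_scen

  annual <- dplyr::summarise(
    dplyr::group_by(by_cm, .data$cell_id),
    pm_base = mean(.data$pm_base), pm_scen = mean(.data$pm_scen),
    d_pm = mean(.data$d_pm), .groups = "drop")
  pop <- cells$population[match(annual$cell_id, cells$cell_id)]
  summary <- tibble::tibble(
    pm_base_area = mean(annual$pm_base),
    pm_scen_area = mean(annual$pm_scen),
    pm_base_pop = sum(annual$pm_base * pop) / sum(pop),
    pm_scen_pop = sum(annual$pm_scen * pop) / sum(pop)
  )
  summary$pct_reduction_area <- 100 * (1 - summary$pm_scen_area / summary$pm_base_area)
  summary$pct_reduction_pop <- 100 * (1 - summary$pm_scen_pop / summary$pm_base_pop)
  structure(list(by_cell_month = by_cm, annual = annual, summary = summary),
            class = "nh3_pm_response")
}

#' PM2.5 control efficiency
#'
#' Percentage reduction of PM2.5 divided by percentage reduction of NH3
#' emissions (%/%).
#'
#' @param pct_pm_reduction Percentage PM2.5 reduction (>= 0).
#' @param pct_nh3_reduction Percentage NH3 emission reduction (> 0).
#' @return The ratio, %/%.
#' @export
#' @examples
#' control_efficiency(19.2, 48.3)  # 0.40
control_efficiency <- function(pct_pm_reduction, pct_nh3_reduction) {
  if (any(pct_nh3_reduction <= 0)) {
    abort_domain("`pct_nh3_reduction` must be > 0")
  }
  pct_pm_reduction / pct_nh3_reduction
}

#' Count heavily polluted days
#'
#' A heavily polluted day has daily mean PM2.5 strictly above the threshold
#' (150 ug/m3 by default).
#'
#' @param daily_pm Numeric vector of daily mean PM2.5, ug/m3.
#' @param threshold Exceedance threshold, ug/m3 (strict `>`).
#' @return Integer count.
#' @export
#' @examples
#' polluted_day_frequency(c(200, 100, 151))  # 2
polluted_day_frequency <- function(daily_pm, threshold = 150) {
  if (length(daily_pm) == 0) abort_domain("`daily_pm` is empty")
  sum(daily_pm > threshold)
}

#' Percentage change in polluted-day counts
#'
#' @param baseline_days,scenario_days Counts from
#'   [polluted_day_frequency()].
#' @return Percentage reduction (positive when the scenario has fewer days).
#' @export
polluted_day_change <- function(baseline_days, scenario_days) {
  if (baseline_days <= 0) abort_domain("baseline has no polluted days")
  100 * (1 - scenario_days / baseline_days)
}

# daily PM series for a set of cells from monthly means and the fixture's
# daily AR(1) log-deviations (mean-one multiplicative factors)
daily_pm_series <- function(pm_monthly, daily_met, sd_log) {
  month_of_day <- rep(1:12, times = month_days)
  key <- paste(daily_met$cell_id, month_of_day[daily_met$day])
  pm_m <- setNames(pm_monthly$pm, paste(pm_monthly$cell_id, pm_monthly$month))
  as.numeric(pm_m[key]) * exp(daily_met$z - sd_log^2 / 2)
}

#' Polluted-day statistics for a scenario
#'
#' Builds per-cell daily PM2.5 series for baseline and scenario by scaling
#' monthly means with the fixture's shared daily meteorological factors, and
#' counts strict exceedances of the threshold.
#'
#' @param response An `nh3_pm_response`.
#' @param fixture The `nh3_region` (must carry `daily_met`).
#' @param params Parameter list.
#' @return Tibble: `days_base`, `days_scen`, `pct_change`.
#' @export
polluted_day_summary <- function(response, fixture, params = nh3_params()) {
  if (is.null(fixture$daily_met)) {
    abort_domain("fixture has no daily meteorology (set daily_met = TRUE)")
  }
  bm <- response$by_cell_month
  sd_log <- fixture$config$met_params$daily_sd /
    sqrt(1 - fixture$config$met_params$daily_rho^2)
  base <- daily_pm_series(
    tibble::tibble(cell_id = bm$cell_id, month = bm$month, pm = bm$pm_base),
    fixture$daily_met, sd_log)
  scen <- daily_pm_series(
    tibble::tibble(cell_id = bm$cell_id, month = bm$month, pm = bm$pm_scen),
    fixture$daily_met, sd_log)
  thr <- params$airq$polluted_day_threshold
  db <- polluted_day_frequency(base, thr)
  ds <- polluted_day_frequency(scen, thr)
  tibble::tibble(days_base = db, days_scen = ds,
                 pct_change = if (db > 0) 100 * (1 - ds / db) else 0)
}

#' Sub-grid heterogeneity experiment (5-km box model)
#'
#' Splits one coarse grid cell into `n_boxes` equal boxes and concentrates
#' the cell's livestock NH3 emission into `k` of them (the remainder of the
#' emission is spread uniformly). In each box, NH3 above a local saturation
#' concentration partially deposits before regional dilution, with deposited
#' fraction `vd / (vd + dilution_rate)` of the excess. The surviving NH3 is
#' then mixed across the cell and fed to the aerosol equilibrium. The
#' underestimation is the relative shortfall of the concentrated case's
#' coarse-cell mean PM2.5 against the uniform case (which a coarse model
#' implicitly assumes): zero at `k = n_boxes`, zero without deposition, and
#' monotone non-decreasing as emissions concentrate into fewer boxes.
#'
#' @param livestock_emission_gg Annual livestock NH3 emission of the coarse
#'   cell, Gg/yr.
#' @param uniform_emission_gg Annual NH3 emission spread uniformly (e.g.
#'   fertilizer + other), Gg/yr.
#' @param cell_area_ha Coarse-cell area, ha.
#' @param concentration_levels Values of `k` (boxes receiving the livestock
#'   emission), between 1 and `n_boxes`.
#' @param n_boxes Number of sub-boxes (100 = a 10 x 10 grid of 5-km boxes in
#'   a 50-km cell).
#' @param temp_k,rh Conditions for the equilibrium.
#' @param params Parameter list (`$airq` supplies dilution, deposition
#'   velocity, saturation and the sulfate/nitrate background).
#' @return Tibble: `k`, `mean_pm`, `underestimation_pct`.
#' @export
subgrid_experiment <- function(livestock_emission_gg = 1.5,
                               uniform_emission_gg = 0.5,
                               cell_area_ha = 250000,
                               concentration_levels = c(100, 25, 4, 1),
                               n_boxes = 100, temp_k = 281, rh = 0.7,
                               params = nh3_params()) {
  if (any(concentration_levels < 1 | concentration_levels > n_boxes)) {
    abort_domain("`concentration_levels` must lie in [1, n_boxes]")
  }
  airq <- params$airq
  box_area <- cell_area_ha / n_boxes
  secs <- 365 * 86400
  vd <- airq$dry_deposition_velocity
  dep_frac <- vd / (vd + airq$dilution_rate)
  conc_unif <- uniform_emission_gg * 1e15 / (cell_area_ha * 1e4) / secs /
    airq$dilution_rate
  run_level <- function(k) {
    liv_box <- c(rep(livestock_emission_gg / k, k), rep(0, n_boxes - k))
    conc_liv <- liv_box * 1e15 / (box_area * 1e4) / secs / airq$dilution_rate
    conc <- conc_unif + conc_liv
    excess <- pmax(0, conc - airq$saturation_nh3)
    surviving <- pmin(conc, airq$saturation_nh3) + excess * (1 - dep_frac)
    mean_nh3 <- mean(surviving)
    eq <- equilibrium_pm(mean_nh3, airq$sulfate_base, airq$nitrate_base,
                         temp_k, rh, airq)
    eq$pm25_inorganic
  }
  pm_uniform <- run_level(n_boxes)
  out <- purrr::map_dfr(sort(concentration_levels, decreasing = TRUE),
                        function(k) {
    pm <- run_level(k)
    tibble::tibble(k = k, mean_pm = pm,
                   underestimation_pct = 100 * (pm_uniform - pm) /
                     pm_uniform)
  })
  out
}
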