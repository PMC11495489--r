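#' Default advanced-technology adoption rates
#'
#' Survey-based adoption rates of advanced nitrogen-management technologies,
#' by sector and farm class. Smallholder crop farms adopt at 22.2%,
#' large-scale crop farms at 43.8%, smallholder (free-range) livestock farms
#' at 19.6% and large-scale livestock farms at 39.1%.
#'
#' @return Named list with elements `crop_smallholder`, `crop_large`,
#'   `livestock_smallholder`, `livestock_large`, each a fraction in `[0, 1]`.
#' @export
#' @examples
#' default_adoption_rates()
default_adoption_rates <- function() {
  list(
    crop_smallholder      = 0.222,
    crop_large            = 0.438,
    livestock_smallholder = 0.196,
    livestock_large       = 0.391
  )
}

# National anchors the default configuration is calibrated against. These are
# the published national statistics for the 2016 baseline; everything below
# derives emission factors and mitigation efficiencies from them so that the
# default synthetic region reproduces the same national accounting identities.
national_anchors <- function() {
  list(
    total_nh3_tg      = 12.8,   # annual NH3, all sectors
    livestock_nh3_tg  = 5.9,    # livestock waste sector
    fertilizer_nh3_tg = 4.9,    # fertilizer application sector
    other_nh3_tg      = 2.0,    # non-agricultural remainder (~15.7%)
    cropland_ha       = 134.9e6,
    mean_n_rate       = 197.8,  # kg N/ha, national mean application rate
    n_rate_decline    = 0.3107, # relative decline under full consolidation
    pig_units_total   = 1.6e9,
    free_range_pu     = 1.0e9,  # smallholder free-range share of pig units
    excretion_n       = 7.2,    # kg N per pig unit per year (7.2 Tg N / 1.0e9 pu)
    slope_exceed      = 0.227,  # cropland fraction steeper than 6 degrees
    sub2ha_mass_share = 0.808,  # cropland mass in parcels < 2 ha, current regime
    large_livestock_post = 0.928 # large-scale pig-unit share after transition
  )
}

#' Default NH3 emission factors
#'
#' Emission-factor set for the EF-times-activity inventory. The fertilizer
#' volatilization fraction and the livestock stage volatilization fractions
#' are calibrated so that, with the default region configuration (134.9 Mha
#' cropland at a mean 197.8 kg N/ha; 1.6 billion pig units excreting
#' 7.2 kg N per pig unit per year), the national annual inventory totals
#' 12.8 Tg NH3 with a 5.9 Tg livestock and 4.9 Tg fertilizer sector
#' (46.1% / 38.2% shares).
#'
#' Stage volatilization fractions are assumptions, not published values: both
#' farm classes volatilize the same total fraction of excreted N, but
#' free-range animals have no housing/storage stages (all N reaches the
#' spreading/grazing stages), while confined large-scale farms emit from
#' housing, storage and spreading.
#'
#' @return List with components `fertilizer_ef`, `excretion_n`,
#'   `stage_fractions` (tibble: `farm_class`, `stage`, `fraction`),
#'   `temperature_sensitivity` (per degree C), `monthly_weights`,
#'   `other_total_gg`, and `uncertainty_gsd` (log-normal geometric SDs per
#'   factor group for Monte Carlo).
#' @export
default_emission_factors <- function() {
  a <- national_anchors()
  # NH3-N volatilized / N applied, from the national fertilizer identity
  fert_ef <- (a$fertilizer_nh3_tg / N_TO_NH3) / (a$mean_n_rate * a$cropland_ha / 1e9)
  # total volatilized fraction of excreted manure N, from the livestock identity
  liv_total <- (a$livestock_nh3_tg / N_TO_NH3) /
    (a$pig_units_total * a$excretion_n / 1e9)
  stage_fractions <- tibble::tibble(
    farm_class = c(rep("large_scale", 3), rep("free_range", 2)),
    stage = c("housing", "storage", "spreading", "spreading", "grazing"),
    # within-class stage shares are assumptions (documented in the vignette)
    fraction = c(
      liv_total * c(0.33, 0.21, 0.46),
      liv_total * c(0.57, 0.43)
    )
  )
  list(
    fertilizer_ef = fert_ef,
    excretion_n = a$excretion_n,
    stage_fractions = stage_fractions,
    temperature_sensitivity = 0.045,
    monthly_weights = rep(1 / 12, 12),
    other_total_gg = a$other_nh3_tg * 1e3,
    uncertainty_gsd = c(fertilizer = 1.25, livestock = 1.18, other = 1.15)
  )
}

#' Default abatement-measure catalog
#'
#' The eight abatement measures: five supply-side technologies acting on the
#' emission factors of the fertilizer or livestock sectors via the
#' adoption-weighted mitigation-efficiency rule, and three demand-side
#' food-loss-and-waste measures that scale activity directly (adoption is
#' identically 1 for demand-side measures).
#'
#' Mitigation efficiencies (`eta`) are calibration constants: each is derived
#' so that, under the current-regime class mix (80.8% smallholder cropland,
#' 62.5% free-range pig units) and the default adoption rates, the measure
#' applied alone to the default region yields the reference national
#' per-measure reduction percentage recorded in `reduction_target_pct`.
#'
#' @return Tibble with columns `id`, `target_group` ("fertilizer" or
#'   "livestock"), `demand_side`, `eta`, `waste_fraction`,
#'   `reduction_target_pct`.
#' @export
default_measure_catalog <- function() {
  a <- national_anchors()
  adopt <- default_adoption_rates()
  fert_share <- a$fertilizer_nh3_tg / a$total_nh3_tg
  liv_share <- a$livestock_nh3_tg / a$total_nh3_tg
  ls_crop0 <- 1 - a$sub2ha_mass_share            # current large-scale cropland share
  ls_liv0 <- 1 - a$free_range_pu / a$pig_units_total
  a_crop0 <- (1 - ls_crop0) * adopt$crop_smallholder + ls_crop0 * adopt$crop_large
  a_liv0 <- (1 - ls_liv0) * adopt$livestock_smallholder + ls_liv0 * adopt$livestock_large

  tech <- tibble::tibble(
    id = c("enhanced_efficiency_fertilizer", "reduce_overuse", "deep_placement",
           "low_crude_protein", "manure_management"),
    target_group = c("fertilizer", "fertilizer", "fertilizer",
                     "livestock", "livestock"),
    demand_side = FALSE,
    reduction_target_pct = c(5.3, 2.7, 4.4, 2.2, 9.7)
  )
  tech$eta <- ifelse(
    tech$target_group == "fertilizer",
    tech$reduction_target_pct / 100 / (a_crop0 * fert_share),
    tech$reduction_target_pct / 100 / (a_liv0 * liv_share)
  )
  tech$waste_fraction <- NA_real_

  demand <- tibble::tibble(
    id = c("reduce_meat_waste", "reduce_staple_waste", "reduce_fruit_veg_waste"),
    target_group = c("livestock", "fertilizer", "fertilizer"),
    demand_side = TRUE,
    reduction_target_pct = c(10.6, 0.8, 1.3)
  )
  demand$eta <- NA_real_
  demand$waste_fraction <- ifelse(
    demand$target_group == "fertilizer",
    demand$reduction_target_pct / 100 / fert_share,
    demand$reduction_target_pct / 100 / liv_share
  )

  dplyr::bind_rows(tech, demand)[, c("id", "target_group", "demand_side",
                                     "eta", "waste_fraction",
                                     "reduction_target_pct")]
}

#' Default GEMM hazard-ratio parameters
#'
#' All-age parameter sets of the Global Exposure Mortality Model for the four
#' causes used here: chronic obstructive pulmonary disease, lung cancer,
#' ischemic heart disease and stroke. Values follow the published GEMM fits
#' (theta with its standard error, and the alpha, mu, nu shape constants);
#' the counterfactual concentration below which no excess risk is assigned
#' is 2.4 ug/m3.
#'
#' @return List with `causes` (tibble: `cause`, `theta`, `se_theta`, `alpha`,
#'   `mu`, `nu`) and `counterfactual` (ug/m3).
#' @export
default_gemm_params <- function() {
  list(
    causes = tibble::tibble(
      cause    = c("copd", "lung_cancer", "ihd", "stroke"),
      theta    = c(0.2510, 0.2942, 0.2969, 0.2720),
      se_theta = c(0.06762, 0.06147, 0.01787, 0.07697),
      alpha    = c(6.5, 6.2, 1.9, 6.2),
      mu       = c(2.5, 9.3, 12.0, 16.7),
      nu       = c(32.0, 29.8, 40.2, 23.7)
    ),
    counterfactual = 2.4
  )
}

#' Default cost-benefit line-item catalog (mid-level parameters)
#'
#' Mid-level cost and benefit line items per scenario, in US$ billions per
#' annum. These are reference accounting data shipped with the package (the
#' health line can instead be recomputed from avoided deaths and the value of
#' a statistical life; see [build_ledger()]). Costs for the demand-side RFLW
#' scenario are absent (`NA`), not zero: quantifying them is out of scope.
#' The "other societal" line is negative because NH3 reductions can worsen
#' acid-rain related damages.
#'
#' @return Tibble with columns `scenario`, `label`, `category`
#'   (cost / private_benefit / societal_benefit) and `value` (US$ bn/yr;
#'   `NA` where not quantified).
#' @export
default_cost_catalog <- function() {
  scen <- c("TECH", "RFLW", "NM", "NMLF-PILOT", "NMLF-ALL")
  row <- function(label, category, values) {
    tibble::tibble(scenario = scen, label = label, category = category,
                   value = values)
  }
  dplyr::bind_rows(
    row("Using enhanced-efficiency fertilizers", "cost",
        c(4.2, NA, 4.1, 4.0, 3.6)),
    row("Deep fertilizer placement", "cost", c(3.6, NA, 3.5, 0.5, 0.6)),
    row("Manure management", "cost", c(7.1, NA, 5.5, 4.2, 3.8)),
    row("Large-scale crop farming", "cost", c(NA, NA, NA, 11.3, 19.4)),
    row("Large-scale livestock farming", "cost", c(NA, NA, NA, 12.1, 24.0)),
    row("Reducing overuse of N fertilizer", "private_benefit",
        c(1.1, NA, 1.1, 4.8, 6.6)),
    row("Deep fertilizer placement", "private_benefit",
        c(2.5, NA, 2.4, 3.2, 3.8)),
    row("Low crude protein feeding", "private_benefit",
        c(2.2, NA, 1.6, 2.1, 2.4)),
    row("Manure management", "private_benefit", c(3.7, NA, 2.8, 4.7, 6.4)),
    row("Large-scale crop farming efficiency gains", "private_benefit",
        c(NA, NA, NA, 8.5, 16.0)),
    row("Large-scale livestock profit expansion", "private_benefit",
        c(NA, NA, NA, 13.3, 25.7)),
    row("Greenhouse gas mitigation benefit", "societal_benefit",
        c(0.8, 2.8, 3.5, 4.6, 7.2)),
    row("Human health benefit", "societal_benefit",
        c(18.6, 12.2, 30.1, 64.0, 75.5)),
    row("Others", "societal_benefit", c(-2.0, -1.2, -2.9, -4.6, -5.5))
  )
}

#' Assemble the full parameter set
#'
#' Bundles every module's default parameters into one nested list, optionally
#' overriding entries from a YAML file or an in-memory list (shallow merge per
#' top-level component).
#'
#' @param overrides Optional named list, or path to a YAML file, with entries
#'   to replace inside the defaults.
#' @return Nested list with components `factors`, `adoption`, `measures`,
#'   `transition`, `airq`, `gemm`, `econ`.
#' @export
#' @examples
#' p <- nh3_params()
#' p$transition$elasticity
nh3_params <- function(overrides = NULL) {
  a <- national_anchors()
  params <- list(
    factors = default_emission_factors(),
    adoption = default_adoption_rates(),
    measures = default_measure_catalog(),
    transition = list(
      slope_max = 6,              # degrees; consolidation blocked above this
      size_threshold = 2,         # ha; large-scale parcel definition
      elasticity = -0.26,         # N-rate vs mean parcel size power law
      n_rate_floor = 50,          # kg N/ha agronomic minimum
      free_range_keep = 0.115,    # fraction of free-range pig units retained
      class_thresholds = c(       # heads per farm for large-scale status
        swine = 500, dairy_cattle = 100, beef_cattle = 100,
        sheep_goats = 1500, layer_poultry = 7500, broiler_poultry = 30000
      )
    ),
    airq = list(
      dilution_rate = 0.01,       # m/s effective ventilation per cell
      background_mixing = 0.3,    # fraction of regional mean entering each cell
      dry_deposition_velocity = 0.02, # m/s for NH3 in the sub-grid box model
      saturation_nh3 = 25,        # ug/m3 local saturation in the box model
      sulfate_base = 8,           # ug/m3 mean sulfate, scaled by pollution weight
      nitrate_base = 12,          # ug/m3 mean total nitrate (as NO3-)
      pm_other_base = 15,         # ug/m3 non-inorganic PM2.5 components
      kp_a = 118.87, kp_b = 24084, kp_c = 6.025, # ln Kp(ppb^2) coefficients
      deliquescence_rh = 0.62,
      polluted_day_threshold = 150 # ug/m3 daily mean, strict exceedance
    ),
    gemm = default_gemm_params(),
    econ = list(
      discount_rate = 0.05,
      lifetime = 20,
      vsl = 250000,               # US$ per statistical life
      scc = 50,                   # US$ per t CO2e
      level = "mid",
      catalog = default_cost_catalog()
    )
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (is.list(params[[nm]]) && is.list(overrides[[nm]])) {
        params[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else {
        params[[nm]] <- overrides[[nm]]
      }
    }
  }
  params
}
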