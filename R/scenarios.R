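#' Apply one abatement measure (adoption-weighted mitigation efficiency)
#'
#' The post-measure emission is
#' `E_r = (1 - adoption) * E + adoption * E * (1 - eta) = E * (1 - adoption * eta)`,
#' i.e. the adopted share of activity emits at the technology's reduced rate
#' while the rest is unchanged. `E_r` always lies in `[E * (1 - eta), E]`.
#'
#' @param E Emission mass (any unit, >= 0); vectorized.
#' @param adoption Adoption fraction in `[0, 1]`.
#' @param eta Mitigation efficiency in `[0, 1]`.
#' @return Post-measure emission, same unit as `E`.
#' @export
#' @examples
#' apply_measure(100, 0.438, 0.5)  # 78.1
apply_measure <- function(E, adoption, eta) {
  check_nonneg(E, "E")
  check_fraction(adoption, "adoption")
  check_fraction(eta, "eta")
  E * (1 - adoption * eta)
}

#' Combine mitigation efficiencies of stacked technologies
#'
#' Multiplicative survival rule: the combined efficiency of technologies with
#' efficiencies `eta_i` is `1 - prod(1 - eta_i)`. Order-independent, bounded
#' by 1, never exceeds the sum of the parts.
#'
#' @param etas Numeric vector of efficiencies in `[0, 1]` (empty gives 0).
#' @return Combined efficiency.
#' @export
#' @examples
#' combine_measures(c(0.5, 0.5))       # 0.75
#' combine_measures(c(0.2, 0.3, 0.1))  # 0.496
combine_measures <- function(etas) {
  if (length(etas) == 0) return(0)
  check_fraction(etas, "etas")
  1 - prod(1 - etas)
}

#' Scenario definitions
#'
#' The five shipped abatement scenarios: TECH (supply-side technologies
#' only), RFLW (demand-side reduced food loss and waste only), NM (their
#' combination) under the current farming regime, and the two
#' nitrogen-management-plus-large-scale-farming scenarios NMLF-PILOT
#' (structural transition in the pilot provinces, N management nationwide)
#' and NMLF-ALL (transition nationwide).
#'
#' @param name Scenario name.
#' @return List: `name`, `measures` (measure ids), `transition` (`NULL`,
#'   `"pilot"` or `"all"`).
#' @export
scenario_definition <- function(name) {
  cat_ids <- default_measure_catalog()$id
  tech <- cat_ids[1:5]
  demand <- cat_ids[6:8]
  defs <- list(
    "TECH" = list(measures = tech, transition = NULL),
    "RFLW" = list(measures = demand, transition = NULL),
    "NM" = list(measures = c(tech, demand), transition = NULL),
    "NMLF-PILOT" = list(measures = c(tech, demand), transition = "pilot"),
    "NMLF-ALL" = list(measures = c(tech, demand), transition = "all")
  )
  if (!name %in% names(defs)) {
    abort_config("scenario", sprintf("unknown scenario `%s`", name))
  }
  c(list(name = name), defs[[name]])
}

# per-cell adoption rates resolved from the (possibly transitioned) farm
# structure: class-share-weighted mix of smallholder and large-scale rates
cell_adoption <- function(fixture, params) {
  cells <- fixture$cells
  cfg <- fixture$config
  bins <- cfg$parcel_size_bins
  lower <- bins[-length(bins)]
  hcols <- paste0("parcel_ha_", seq_len(length(bins) - 1))
  h <- as.matrix(cells[, hcols])
  tot <- rowSums(h)
  ls_crop <- ifelse(tot > 0, rowSums(h[, lower >= 2, drop = FALSE]) / tot, 0)
  ad <- params$adoption
  a_crop <- (1 - ls_crop) * ad$crop_smallholder + ls_crop * ad$crop_large

  farms <- fixture$farms
  pu <- farms_pig_units(farms)
  pu_tot <- tapply(pu, farms$cell_id, sum)
  pu_large <- tapply(pu * (farms$farm_class == "large_scale"), farms$cell_id, sum)
  ls_liv <- rep(0, nrow(cells))
  idx <- as.integer(names(pu_tot))
  ls_liv[match(idx, cells$cell_id)] <-
    ifelse(pu_tot > 0, pu_large / pu_tot, 0)
  a_liv <- (1 - ls_liv) * ad$livestock_smallholder + ls_liv * ad$livestock_large
  tibble::tibble(cell_id = cells$cell_id, adoption_fertilizer = a_crop,
                 adoption_livestock = a_liv)
}

#' Build an abatement scenario
#'
#' Applies a scenario to the region: for NMLF scenarios the farm-structure
#' transition is applied first ([apply_transition()]) and the activity-based
#' inventory recomputed (lower N rates, relocated livestock); demand-side
#' measures then scale the fertilizer/livestock activity by the configured
#' waste-reduction fractions; finally the supply-side technologies act
#' through the adoption-weighted mitigation-efficiency rule with the
#' per-cell adoption rates resolved from the (possibly transitioned) farm
#' structure, combining stacked technologies multiplicatively.
#'
#' @param name Scenario name (see [scenario_definition()]), or a custom
#'   definition list with elements `name`, `measures`, `transition`.
#' @param fixture The current-regime `nh3_region`.
#' @param baseline Baseline `nh3_emission_field`; computed from `fixture`
#'   when `NULL`.
#' @param params Parameter list from [nh3_params()].
#' @return List of class `nh3_scenario`: `name`, `baseline`, `emissions`
#'   (the reduced field `E_r`), `fixture_used`, `per_measure` (per-measure
#'   national reduction percentages), `transition_summary` (or `NULL`).
#' @export
build_scenario <- function(name, fixture, baseline = NULL,
                           params = nh3_params()) {
  def <- if (is.list(name)) name else scenario_definition(name)
  catalog <- params$measures
  unknown <- setdiff(def$measures, catalog$id)
  if (length(unknown)) {
    abort_config("measures", sprintf("unknown measure id `%s`", unknown[1]))
  }
  if (is.null(baseline)) baseline <- total_inventory(fixture, params$factors)

  trans_summary <- NULL
  fixture_used <- fixture
  if (!is.null(def$transition)) {
    fixture_used <- apply_transition(fixture, def$transition, params)
    trans_summary <- attr(fixture_used, "transition_summary")
    active <- total_inventory(fixture_used, params$factors)
  } else {
    active <- baseline
  }

  meas <- catalog[catalog$id %in% def$measures, ]
  sector_group <- function(sector) {
    ifelse(sector == "fertilizer", "fertilizer",
           ifelse(startsWith(sector, "livestock_"), "livestock", "other"))
  }
  grp <- sector_group(active$sector)

  # demand-side activity scaling
  scale_f <- prod(1 - meas$waste_fraction[meas$demand_side &
                                            meas$target_group == "fertilizer"])
  scale_l <- prod(1 - meas$waste_fraction[meas$demand_side &
                                            meas$target_group == "livestock"])
  e_scaled <- active$emission_gg *
    ifelse(grp == "fertilizer", scale_f, ifelse(grp == "livestock", scale_l, 1))

  # technology measures via adoption-weighted combined efficiency
  eta_f <- combine_measures(meas$eta[!meas$demand_side &
                                       meas$target_group == "fertilizer"])
  eta_l <- combine_measures(meas$eta[!meas$demand_side &
                                       meas$target_group == "livestock"])
  adopt <- cell_adoption(fixture_used, params)
  a_f <- adopt$adoption_fertilizer[match(active$cell_id, adopt$cell_id)]
  a_l <- adopt$adoption_livestock[match(active$cell_id, adopt$cell_id)]
  e_r <- e_scaled * ifelse(grp == "fertilizer", 1 - a_f * eta_f,
                           ifelse(grp == "livestock", 1 - a_l * eta_l, 1))

  emissions <- active
  emissions$emission_gg <- e_r

  # per-measure national reductions (each measure alone on the scenario's
  # activity field), as % of the original baseline total
  base_total <- sum(baseline$emission_gg)
  per_measure <- purrr::map_dfr(seq_len(nrow(meas)), function(i) {
    m <- meas[i, ]
    g_mask <- grp == m$target_group
    if (m$demand_side) {
      red <- sum(active$emission_gg[g_mask]) * m$waste_fraction
    } else {
      a <- if (m$target_group == "fertilizer") a_f else a_l
      red <- sum(active$emission_gg[g_mask] * a[g_mask] * m$eta)
    }
    tibble::tibble(id = m$id, target_group = m$target_group,
                   reduction_pct = 100 * red / base_total)
  })

  structure(list(name = def$name, baseline = baseline, emissions = emissions,
                 fixture_used = fixture_used, per_measure = per_measure,
                 transition_summary = trans_summary),
            class = "nh3_scenario")
}

#' Reduction summary of a scenario over region masks
#'
#' Percentage emission reduction `100 * (1 - sum(E_r) / sum(E))` per mask and
#' sector group.
#'
#' @param result An `nh3_scenario`.
#' @param masks Named list of cell-id vectors; defaults to `national` (all
#'   cells) and `pilot` (pilot-province cells of the fixture used).
#' @return Tibble: `mask`, `group` (`total`, `fertilizer`, `livestock`),
#'   `reduction_pct`.
#' @export
reduction_summary <- function(result, masks = NULL) {
  stopifnot(inherits(result, "nh3_scenario"))
  cells <- result$fixture_used$cells
  if (is.null(masks)) {
    masks <- list(national = cells$cell_id,
                  pilot = cells$cell_id[cells$is_pilot])
  }
  base <- result$baseline
  scen <- result$emissions
  grp <- ifelse(base$sector == "fertilizer", "fertilizer",
                ifelse(startsWith(base$sector, "livestock_"), "livestock",
                       "other"))
  purrr::map_dfr(names(masks), function(mn) {
    ids <- masks[[mn]]
    if (length(ids) == 0) abort_domain(sprintf("mask `%s` is empty", mn))
    in_mask_b <- base$cell_id %in% ids
    in_mask_s <- scen$cell_id %in% ids
    one <- function(gname, sel_b, sel_s) {
      eb <- sum(base$emission_gg[sel_b])
      es <- sum(scen$emission_gg[sel_s])
      tibble::tibble(mask = mn, group = gname,
                     reduction_pct = 100 * (1 - es / eb))
    }
    dplyr::bind_rows(
      one("total", in_mask_b, in_mask_s),
      one("fertilizer", in_mask_b & grp == "fertilizer",
          in_mask_s & grp == "fertilizer"),
      one("livestock", in_mask_b & startsWith(base$sector, "livestock_"),
          in_mask_s & startsWith(scen$sector, "livestock_"))
    )
  })
}

#' @export
print.nh3_scenario <- function(x, ...) {
  nat <- reduction_summary(x)
  tot <- nat$reduction_pct[nat$mask == "national" & nat$group == "total"]
  cat(sprintf("<nh3_scenario> %s: national NH3 reduction %.1f%%\n",
              x$name, tot))
  invisible(x)
}
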