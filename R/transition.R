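#' Pig-unit conversion factors
#'
#' Common livestock denominator: one head of swine is 1 pig unit; one head of
#' dairy cattle, beef cattle, sheep/goats, layer poultry and broiler poultry
#' is 10, 5, 1/3, 1/15 and 1/60 pig units respectively.
#'
#' @return Named numeric vector of pig units per head.
#' @export
pig_unit_factors <- function() {
  c(swine = 1, dairy_cattle = 10, beef_cattle = 5, sheep_goats = 1 / 3,
    layer_poultry = 1 / 15, broiler_poultry = 1 / 60)
}

#' Convert heads by species to pig units
#'
#' @param heads_by_species Named numeric (heads per species); names must be
#'   known species.
#' @param factors Conversion factors, see [pig_unit_factors()].
#' @return Total pig units.
#' @export
#' @examples
#' pig_units(c(dairy_cattle = 10))            # 100
#' pig_units(c(broiler_poultry = 60, sheep_goats = 3))  # 2
pig_units <- function(heads_by_species, factors = pig_unit_factors()) {
  if (length(heads_by_species) == 0) return(0)
  unknown <- setdiff(names(heads_by_species), names(factors))
  if (length(unknown)) {
    abort_domain(sprintf("unknown species `%s`", unknown[1]))
  }
  check_nonneg(unlist(heads_by_species), "heads")
  sum(unlist(heads_by_species) * factors[names(heads_by_species)])
}

# vectorized pig units for a farms tibble
farms_pig_units <- function(farms, factors = pig_unit_factors()) {
  if (nrow(farms) == 0) return(numeric())
  pu <- rep(0, nrow(farms))
  for (s in intersect(names(factors), names(farms))) {
    pu <- pu + farms[[s]] * factors[[s]]
  }
  pu
}

#' Consolidate a parcel-size histogram under a terrain constraint
#'
#' In cells with slope at or below `slope_max`, all cropland mass in parcels
#' below `size_threshold` is merged into the smallest bin whose lower edge is
#' at least the threshold; on steeper terrain the histogram is unchanged
#' (consolidation and mechanization are not cost-effective there). Total
#' cropland mass is conserved exactly.
#'
#' @param histogram Numeric vector of cropland mass (ha) per bin.
#' @param slope Cell slope, degrees.
#' @param bins Bin edges (length `length(histogram) + 1`).
#' @param slope_max Maximum slope for consolidation, degrees.
#' @param size_threshold Large-scale parcel threshold, ha (must be a bin edge).
#' @return Consolidated histogram (ha per bin).
#' @export
#' @examples
#' consolidate_parcels(c(0, 0, 100, 50, 0, 0), slope = 2)
consolidate_parcels <- function(histogram, slope,
                                bins = c(0, 0.5, 1, 2, 5, 10, 50),
                                slope_max = 6, size_threshold = 2) {
  if (slope < 0) abort_domain("`slope` must be >= 0")
  if (slope > slope_max) return(histogram)
  lower <- bins[-length(bins)]
  target_bin <- which(lower >= size_threshold)[1]
  if (is.na(target_bin)) abort_domain("no bin at or above `size_threshold`")
  small <- which(lower < size_threshold)
  out <- histogram
  out[target_bin] <- out[target_bin] + sum(histogram[small])
  out[small] <- 0
  out
}

#' Mean parcel size of a mass histogram
#'
#' Parcel counts per bin are the bin mass divided by the bin midpoint; the
#' mean parcel size is total mass over total count.
#'
#' @inheritParams consolidate_parcels
#' @return Mean parcel size, ha.
#' @export
parcel_mean_size <- function(histogram, bins = c(0, 0.5, 1, 2, 5, 10, 50)) {
  mid <- (bins[-1] + bins[-length(bins)]) / 2
  total <- sum(histogram)
  if (total <= 0) abort_domain("histogram has zero cropland mass")
  total / sum(histogram / mid)
}

#' Large-scale cropland fraction of a histogram
#'
#' Mass in bins at or above the size threshold divided by total mass.
#' @inheritParams consolidate_parcels
#' @return Fraction in `[0, 1]` (0 for an empty histogram).
#' @export
large_scale_fraction <- function(histogram, bins = c(0, 0.5, 1, 2, 5, 10, 50),
                                 size_threshold = 2) {
  total <- sum(histogram)
  if (total <= 0) return(0)
  lower <- bins[-length(bins)]
  sum(histogram[lower >= size_threshold]) / total
}

#' N application rate after a farm-size change
#'
#' Fertilizer intensity declines with farm size following a power law:
#' `new_rate = old_rate * (mean_size_after / mean_size_before)^elasticity`,
#' floored at an agronomic minimum. With an unchanged histogram, or zero
#' elasticity, the rate is unchanged. The default elasticity (-0.26) is a
#' calibration constant chosen so the default region's national mean rate
#' falls by about 31% under full consolidation.
#'
#' @param n_rate Current rate, kg N/ha.
#' @param hist_before,hist_after Parcel histograms before/after consolidation.
#' @param bins Bin edges.
#' @param elasticity Power-law exponent, must be <= 0.
#' @param floor Agronomic minimum rate, kg N/ha.
#' @return New rate, kg N/ha.
#' @export
#' @examples
#' # a 4-fold mean-size increase with elasticity -0.27 multiplies the rate
#' # by 4^-0.27 = 0.688
n_rate_after <- function(n_rate, hist_before, hist_after,
                         bins = c(0, 0.5, 1, 2, 5, 10, 50),
                         elasticity = -0.26, floor = 0) {
  if (elasticity > 0) abort_domain("`elasticity` must be <= 0")
  m0 <- parcel_mean_size(hist_before, bins)
  m1 <- parcel_mean_size(hist_after, bins)
  max(floor, n_rate * (m1 / m0)^elasticity)
}

#' Reallocate free-range livestock to large-scale farms within provinces
#'
#' Moves free-range pig units (optionally keeping a residual fraction
#' free-range) onto the large-scale farms of the same province,
#' proportionally to existing farm capacity. Heads are moved species-wise:
#' departing free-range farms are scaled down uniformly, and each recipient
#' farm's head vector is scaled up so its pig-unit gain matches its
#' proportional share. Provinces without any large-scale farm get one new
#' farm point seeded at the cell with the most free-range pig units.
#' Per-province pig-unit totals are conserved exactly.
#'
#' @param farms Farms tibble (`farm_id`, `cell_id`, `farm_class`, one column
#'   of heads per species).
#' @param province_map Tibble with `cell_id`, `province_id` covering every
#'   farm's cell.
#' @param keep_fraction Fraction of free-range pig units left in place
#'   (0 = full reallocation).
#' @param provinces Optional subset of province ids to reallocate (others
#'   untouched).
#' @param allow_new Create a new farm point when a province has no
#'   large-scale farm? If `FALSE`, such a province raises an error.
#' @return Farms tibble after reallocation.
#' @export
reallocate_livestock <- function(farms, province_map, keep_fraction = 0,
                                 provinces = NULL, allow_new = TRUE) {
  check_fraction(keep_fraction, "keep_fraction")
  if (nrow(farms) == 0) return(farms)
  miss <- setdiff(unique(farms$cell_id), province_map$cell_id)
  if (length(miss)) {
    abort_domain("every farm must be assigned a province via `province_map`")
  }
  prov <- province_map$province_id[match(farms$cell_id, province_map$cell_id)]
  if (is.null(provinces)) provinces <- unique(prov)
  species <- intersect(names(pig_unit_factors()), names(farms))
  pu <- farms_pig_units(farms)
  out <- farms
  new_rows <- list()
  for (pv in provinces) {
    idx_free <- which(prov == pv & farms$farm_class == "free_range")
    idx_large <- which(prov == pv & farms$farm_class == "large_scale")
    moved_pu <- sum(pu[idx_free]) * (1 - keep_fraction)
    if (moved_pu <= 0) next
    # species-wise moved heads
    moved_heads <- sapply(species, function(s) {
      sum(farms[[s]][idx_free]) * (1 - keep_fraction)
    })
    for (s in species) {
      out[[s]][idx_free] <- out[[s]][idx_free] * keep_fraction
    }
    if (length(idx_large) == 0) {
      if (!allow_new) {
        abort_domain(sprintf(
          "province %s has no large-scale farm to receive reallocated livestock",
          pv))
      }
      seed_cell <- farms$cell_id[idx_free][which.max(pu[idx_free])]
      row <- tibble::tibble(farm_id = NA_integer_, cell_id = seed_cell,
                            farm_class = "large_scale")
      for (s in species) row[[s]] <- moved_heads[[s]]
      new_rows[[length(new_rows) + 1]] <- row
    } else {
      cap <- pu[idx_large]
      share <- cap / sum(cap)
      # scale each recipient's head vector so its pig units grow by its share
      growth <- 1 + moved_pu * share / cap
      for (s in species) {
        out[[s]][idx_large] <- out[[s]][idx_large] * growth
      }
    }
  }
  if (length(new_rows)) {
    out <- dplyr::bind_rows(out, dplyr::bind_rows(new_rows))
    out$farm_id <- seq_len(nrow(out))
  }
  out
}

#' Apply the smallholder-to-large-scale transition to a fixture
#'
#' Runs the three transition rules over the masked provinces: parcel
#' consolidation under the 6-degree terrain constraint, the power-law N-rate
#' decline (floored), and reallocation of free-range livestock to
#' large-scale point sources within each province. Cropland and pig units
#' are conserved.
#'
#' @param fixture An `nh3_region`.
#' @param regime `"all"` (nationwide) or `"pilot"` (pilot provinces only).
#' @param params Parameter list, see [nh3_params()] (`$transition` is used).
#' @return A list of class `nh3_region` with the transitioned `cells` and
#'   `farms`, plus attribute `"transition_summary"`.
#' @export
apply_transition <- function(fixture, regime = c("all", "pilot"),
                             params = nh3_params()) {
  regime <- match.arg(regime)
  tp <- params$transition
  cells <- fixture$cells
  cfg <- fixture$config
  bins <- cfg$parcel_size_bins
  nb <- length(bins) - 1
  hcols <- paste0("parcel_ha_", seq_len(nb))
  mask <- if (regime == "pilot") cells$is_pilot else rep(TRUE, nrow(cells))

  hist_before <- as.matrix(cells[, hcols])
  hist_after <- hist_before
  n_rate_new <- cells$n_rate
  for (i in which(mask)) {
    h1 <- consolidate_parcels(hist_before[i, ], cells$slope_deg[i], bins,
                              tp$slope_max, tp$size_threshold)
    hist_after[i, ] <- h1
    if (sum(hist_before[i, ]) > 0 && any(h1 != hist_before[i, ])) {
      n_rate_new[i] <- n_rate_after(cells$n_rate[i], hist_before[i, ], h1,
                                    bins, tp$elasticity, tp$n_rate_floor)
    }
  }
  cells_new <- cells
  cells_new[, hcols] <- hist_after
  cells_new$n_rate <- n_rate_new

  pmap <- cells[, c("cell_id", "province_id")]
  mask_prov <- unique(cells$province_id[mask])
  farms_new <- reallocate_livestock(fixture$farms, pmap,
                                    keep_fraction = tp$free_range_keep,
                                    provinces = mask_prov)

  ls_frac <- function(h) {
    lower <- bins[-length(bins)]
    sum(h[, lower >= tp$size_threshold]) / sum(h)
  }
  pu_new <- farms_pig_units(farms_new)
  summary <- list(
    regime = regime,
    large_scale_crop_fraction_before = ls_frac(hist_before),
    large_scale_crop_fraction_after = ls_frac(hist_after),
    mean_n_rate_before = sum(cells$n_rate * cells$cropland_ha) /
      sum(cells$cropland_ha),
    mean_n_rate_after = sum(n_rate_new * cells_new$cropland_ha) /
      sum(cells_new$cropland_ha),
    large_livestock_share_after =
      sum(pu_new[farms_new$farm_class == "large_scale"]) / sum(pu_new)
  )
  out <- fixture
  out$cells <- cells_new
  out$farms <- farms_new
  attr(out, "transition_summary") <- summary
  out
}
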