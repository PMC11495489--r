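#' GEMM hazard ratio
#'
#' Global Exposure Mortality Model hazard-ratio curve:
#' `HR(z) = exp(theta * log(z/alpha + 1) / (1 + exp(-(z - mu)/nu)))` with
#' `z = max(0, pm - counterfactual)`. HR is exactly 1 at or below the
#' counterfactual concentration and strictly increasing above it.
#'
#' @param pm PM2.5 concentration, ug/m3 (vectorized, finite, >= 0).
#' @param theta,alpha,mu,nu GEMM shape parameters (see
#'   [default_gemm_params()]).
#' @param counterfactual Concentration below which no excess risk accrues,
#'   ug/m3.
#' @return Hazard ratio (>= 1).
#' @export
#' @examples
#' gemm_hazard_ratio(12.4, theta = 0.1, alpha = 1, mu = 10, nu = 5)  # 1.1273
gemm_hazard_ratio <- function(pm, theta, alpha, mu, nu, counterfactual = 2.4) {
  if (any(!is.finite(pm))) abort_domain("`pm` must be finite")
  if (any(pm < 0)) abort_domain("`pm` must be >= 0")
  z <- pmax(0, pm - counterfactual)
  exp(theta * log(z / alpha + 1) / (1 + exp(-(z - mu) / nu)))
}

#' PM2.5-attributable premature deaths
#'
#' Per cell and cause, attributable deaths are
#' `population * baseline_rate * (1 - 1/HR(pm))`: the attributable fraction
#' of the cause-specific baseline mortality. Attributable deaths are always
#' within `[0, baseline deaths)`.
#'
#' @param pm_annual Tibble with `cell_id`, `pm` (annual mean PM2.5, ug/m3).
#' @param cells Cells tibble carrying `population` and `mort_<cause>`
#'   columns.
#' @param gemm GEMM parameter list (see [default_gemm_params()]).
#' @return Tibble of class `nh3_mortality`: `cell_id`, `cause`,
#'   `baseline_deaths`, `attributable_deaths` (per year).
#' @export
attributable_deaths <- function(pm_annual, cells,
                                gemm = default_gemm_params()) {
  idx <- match(pm_annual$cell_id, cells$cell_id)
  if (any(is.na(idx))) abort_domain("pm grid and cells are not aligned")
  pop <- cells$population[idx]
  check_nonneg(pop, "population")
  out <- purrr::map_dfr(seq_len(nrow(gemm$causes)), function(i) {
    p <- gemm$causes[i, ]
    rate <- cells[[paste0("mort_", p$cause)]][idx]
    check_nonneg(rate, paste0("mort_", p$cause))
    hr <- gemm_hazard_ratio(pm_annual$pm, p$theta, p$alpha, p$mu, p$nu,
                            gemm$counterfactual)
    tibble::tibble(
      cell_id = pm_annual$cell_id, cause = p$cause,
      baseline_deaths = pop * rate,
      attributable_deaths = pop * rate * (1 - 1 / hr)
    )
  })
  structure(out, class = c("nh3_mortality", class(out)))
}

#' Avoided premature deaths of a scenario against a reference
#'
#' Sum over cells and causes of the difference in attributable deaths.
#' Non-negative for any scenario that only lowers PM2.5.
#'
#' @param reference,scenario `nh3_mortality` tables on the same grid and
#'   causes.
#' @return List: `total` (deaths/yr) and `by_cause` tibble.
#' @export
avoided_deaths <- function(reference, scenario) {
  if (nrow(reference) != nrow(scenario) ||
      !all(reference$cell_id == scenario$cell_id) ||
      !all(reference$cause == scenario$cause)) {
    abort_domain("mortality tables are not on the same grid and causes")
  }
  d <- reference$attributable_deaths - scenario$attributable_deaths
  by_cause <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cause = reference$cause, d = d),
                    .data$cause),
    avoided = sum(.data$d), .groups = "drop")
  list(total = sum(d), by_cause = by_cause)
}
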