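#' Annualized cost of an investment (capital recovery factor)
#'
#' `I * r(1+r)^lt / ((1+r)^lt - 1) + FVO`: the upfront investment converted
#' to an equivalent annual payment over the technique lifetime at discount
#' rate `r`, plus annual fixed and variable operating costs. Below
#' `r = 1e-9` the analytic limit `I/lt + FVO` is used.
#'
#' @param I Upfront investment (>= 0).
#' @param r Discount rate, fraction/yr.
#' @param lt Technique lifetime, years (>= 1).
#' @param FVO Annual fixed and variable operating costs (>= 0).
#' @return Annualized cost, same currency unit as `I` per year.
#' @export
#' @examples
#' annualized_cost(100, 0.05, 20)  # 8.0243
annualized_cost <- function(I, r, lt, FVO = 0) {
  check_nonneg(I, "I")
  check_nonneg(FVO, "FVO")
  if (any(lt < 1)) abort_domain("`lt` must be >= 1 year")
  if (any(r < 0)) abort_domain("`r` must be >= 0")
  crf <- ifelse(r < 1e-9, 1 / lt, r * (1 + r)^lt / ((1 + r)^lt - 1))
  I * crf + FVO
}

#' Monetize avoided premature deaths
#'
#' @param avoided_deaths Deaths per year (>= 0).
#' @param vsl Value of a statistical life, US$ (default 250,000).
#' @return US$ billions per year.
#' @export
#' @examples
#' health_valuation(256000)  # 64.0
health_valuation <- function(avoided_deaths, vsl = 250000) {
  check_nonneg(avoided_deaths, "avoided_deaths")
  check_nonneg(vsl, "vsl")
  avoided_deaths * vsl / 1e9
}

#' Build a scenario cost-benefit ledger
#'
#' Assembles the line items of one scenario from the item catalog (costs,
#' private benefits and societal benefits in US$ bn/yr). The human health
#' line is recomputed as `avoided_deaths * vsl` when avoided deaths are
#' supplied, and the greenhouse-gas line as `ghg_reduction * scc` when a
#' CO2e reduction is supplied; otherwise the catalog values are used.
#' Totals per category, the net benefit
#' (`private + societal - costs`) and the benefit-cost ratio follow by
#' identity. Scenarios with no costed items (RFLW) carry `NA` costs —
#' absent, not zero — and no benefit-cost ratio.
#'
#' @param scenario Scenario name present in the catalog.
#' @param avoided_deaths Optional deaths/yr to recompute the health line.
#' @param ghg_reduction Optional t CO2e/yr reduction to recompute the GHG
#'   line.
#' @param params Parameter list ([nh3_params()]`$econ` supplies `vsl`,
#'   `scc` and the catalog).
#' @return List of class `nh3_ledger`: `scenario`, `items`, `totals`
#'   (costs, private, societal), `net_benefit`, `bcr` (`NA` when costs are
#'   absent).
#' @export
#' @examples
#' led <- build_ledger("NMLF-PILOT")
#' led$net_benefit  # 68.4
build_ledger <- function(scenario, avoided_deaths = NULL, ghg_reduction = NULL,
                         params = nh3_params()) {
  catalog <- params$econ$catalog
  items <- catalog[catalog$scenario == scenario, ]
  if (nrow(items) == 0) {
    abort_config("scenario", sprintf("no catalog entries for `%s`", scenario))
  }
  if (!is.null(avoided_deaths)) {
    items$value[items$label == "Human health benefit"] <-
      health_valuation(avoided_deaths, params$econ$vsl)
  }
  if (!is.null(ghg_reduction)) {
    items$value[items$label == "Greenhouse gas mitigation benefit"] <-
      ghg_reduction * params$econ$scc / 1e9
  }
  tot <- function(cat) {
    v <- items$value[items$category == cat]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }
  costs <- tot("cost")
  private <- tot("private_benefit")
  societal <- tot("societal_benefit")
  benefits <- sum(c(private, societal), na.rm = TRUE)
  net <- benefits - if (is.na(costs)) 0 else costs
  bcr <- if (is.na(costs) || costs <= 0) NA_real_ else benefits / costs
  structure(list(
    scenario = scenario, items = items,
    totals = c(costs = costs, private_benefit = private,
               societal_benefit = societal, benefits = benefits),
    net_benefit = net, bcr = bcr
  ), class = "nh3_ledger")
}

#' Benefit-cost ratio of a ledger
#'
#' Total benefits (private + societal) divided by total costs. Errors when
#' the ledger has zero or absent costs (demand-side scenarios whose costs
#' were not quantified report no ratio).
#'
#' @param ledger An `nh3_ledger`.
#' @return The ratio.
#' @export
#' @examples
#' benefit_cost_ratio(build_ledger("NMLF-PILOT"))  # 3.13
benefit_cost_ratio <- function(ledger) {
  costs <- ledger$totals[["costs"]]
  if (is.na(costs) || costs <= 0) {
    abort_domain("ledger has zero or absent costs; no benefit-cost ratio")
  }
  ledger$totals[["benefits"]] / costs
}

#' @export
print.nh3_ledger <- function(x, ...) {
  cat(sprintf("<nh3_ledger> %s (US$ bn/yr)\n", x$scenario))
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  cat("  total costs:            ", fmt(x$totals[["costs"]]), "\n")
  cat("  total private benefits: ", fmt(x$totals[["private_benefit"]]), "\n")
  cat("  total societal benefits:", fmt(x$totals[["societal_benefit"]]), "\n")
  cat("  net benefit:            ", fmt(x$net_benefit), "\n")
  bcr_txt <- if (is.na(x$bcr)) "-" else sprintf("%.2f", round(x$bcr, 2))
  cat("  benefit-cost ratio:     ", bcr_txt, "\n")
  invisible(x)
}

#' Ledger report across scenarios
#'
#' Wide table mirroring the canonical cost-benefit layout: one row per line
#' item and per category total, one column per scenario.
#'
#' @param ledgers List of `nh3_ledger`s.
#' @return Tibble.
#' @export
ledger_report <- function(ledgers) {
  long <- purrr::map_dfr(ledgers, function(l) {
    dplyr::bind_rows(
      l$items[, c("label", "category", "value")] |>
        dplyr::mutate(scenario = l$scenario),
      tibble::tibble(
        label = c("Total costs", "Total private benefits",
                  "Total societal benefits", "Net benefits"),
        category = "total",
        value = c(l$totals[["costs"]], l$totals[["private_benefit"]],
                  l$totals[["societal_benefit"]], l$net_benefit),
        scenario = l$scenario
      )
    )
  })
  tidyr::pivot_wider(long, names_from = "scenario", values_from = "value")
}
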