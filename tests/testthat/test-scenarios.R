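test_that("the adoption-weighted measure rule gives the closed form", {
  expect_equal(apply_measure(100, 0, 0.9), 100)
  expect_equal(apply_measure(100, 1, 1), 0)
  expect_equal(apply_measure(100, 0.438, 0.5), 78.1)
  expect_error(apply_measure(-1, 0.5, 0.5), "E")
  expect_error(apply_measure(1, 1.2, 0.5), "adoption")
  expect_error(apply_measure(1, 0.5, -0.1), "eta")
})

test_that("stacked efficiencies combine multiplicatively", {
  expect_equal(combine_measures(c(0.5, 0.5)), 0.75)
  expect_equal(combine_measures(c(0.2, 0.3, 0.1)), 0.496)
  expect_equal(combine_measures(0.37), 0.37)
  expect_equal(combine_measures(numeric()), 0)
  # commutative, bounded by 1 and by the sum
  set.seed(8)
  for (i in 1:50) {
    etas <- runif(sample(2:5, 1))
    expect_equal(combine_measures(etas), combine_measures(rev(etas)))
    expect_lte(combine_measures(etas), min(1, sum(etas)))
  }
})

test_that("a scenario without measures reduces nothing", {
  r <- small_region(seed = 41)
  sc <- build_scenario(list(name = "NOOP", measures = character(),
                            transition = NULL), r)
  expect_equal(sc$emissions$emission_gg, sc$baseline$emission_gg)
  rs <- reduction_summary(sc)
  expect_equal(rs$reduction_pct, rep(0, nrow(rs)))
})

test_that("a single measure at uniform adoption reduces its sector by a*eta", {
  r <- small_region(seed = 42)
  params <- nh3_params()
  a <- 0.3
  params$adoption <- list(crop_smallholder = a, crop_large = a,
                          livestock_smallholder = a, livestock_large = a)
  params$measures <- tibble::tibble(
    id = "enhanced_efficiency_fertilizer", target_group = "fertilizer",
    demand_side = FALSE, eta = 0.5, waste_fraction = NA_real_,
    reduction_target_pct = NA_real_)
  sc <- build_scenario(list(name = "ONE",
                            measures = "enhanced_efficiency_fertilizer",
                            transition = NULL), r, params = params)
  rs <- reduction_summary(sc)
  expect_equal(rs$reduction_pct[rs$mask == "national" &
                                  rs$group == "fertilizer"],
               100 * a * 0.5, tolerance = 1e-9)
  expect_error(build_scenario(list(name = "X", measures = "warp_drive",
                                   transition = NULL), r, params = params),
               "unknown measure")
})

test_that("reduction summaries aggregate mask emissions correctly", {
  r <- small_region(seed = 43)
  base <- total_inventory(r)
  # toy: halve one cell's emissions, keep another fixed
  scen <- base
  scen$emission_gg[scen$cell_id == 1] <- scen$emission_gg[scen$cell_id == 1] * 0.5
  sc <- structure(list(name = "toy", baseline = base, emissions = scen,
                       fixture_used = r), class = "nh3_scenario")
  e1 <- sum(base$emission_gg[base$cell_id == 1])
  e2 <- sum(base$emission_gg[base$cell_id == 2])
  rs <- reduction_summary(sc, masks = list(two_cells = c(1L, 2L)))
  expect_equal(rs$reduction_pct[rs$group == "total"],
               100 * (1 - (0.5 * e1 + e2) / (e1 + e2)), tolerance = 1e-12)
  expect_error(reduction_summary(sc, masks = list(nothing = integer())),
               "empty")
  # E_r = E gives 0%; E_r = 0 gives 100%
  sc0 <- sc; sc0$emissions$emission_gg <- 0
  rs0 <- reduction_summary(sc0)
  expect_equal(rs0$reduction_pct[rs0$group == "total" &
                                   rs0$mask == "national"], 100)
})

test_that("shipped scenarios respect the cell-wise bound under a fixed structure", {
  r <- small_region(seed = 44)
  base <- total_inventory(r)
  for (nm in c("TECH", "RFLW", "NM")) {
    sc <- build_scenario(nm, r, base)
    expect_true(all(sc$emissions$emission_gg <= base$emission_gg + 1e-12),
                label = nm)
    expect_true(all(sc$emissions$emission_gg >= 0), label = nm)
  }
})

test_that("combined scenarios nest: NM dominates TECH and RFLW per cell", {
  r <- small_region(seed = 45)
  base <- total_inventory(r)
  cell_total <- function(sc) {
    tapply(sc$emissions$emission_gg, sc$emissions$cell_id, sum)
  }
  tech <- cell_total(build_scenario("TECH", r, base))
  rflw <- cell_total(build_scenario("RFLW", r, base))
  nm <- cell_total(build_scenario("NM", r, base))
  expect_true(all(nm <= tech + 1e-12))
  expect_true(all(nm <= rflw + 1e-12))
})

test_that("doubling adoption doubles a small measure's reduction to first order", {
  r <- small_region(seed = 46)
  params <- nh3_params()
  meas <- tibble::tibble(id = "m", target_group = "fertilizer",
                         demand_side = FALSE, eta = 0.05,
                         waste_fraction = NA_real_,
                         reduction_target_pct = NA_real_)
  params$measures <- meas
  red_at <- function(a) {
    params$adoption <- list(crop_smallholder = a, crop_large = a,
                            livestock_smallholder = a, livestock_large = a)
    sc <- build_scenario(list(name = "m", measures = "m", transition = NULL),
                         r, params = params)
    rs <- reduction_summary(sc)
    rs$reduction_pct[rs$mask == "national" & rs$group == "total"]
  }
  r1 <- red_at(0.05); r2 <- red_at(0.10)
  expect_lt(abs(r2 / r1 - 2), 0.05 * 2)
})
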