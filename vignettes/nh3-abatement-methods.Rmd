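---
title: "Methods: integrated assessment of agricultural ammonia abatement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated assessment of agricultural ammonia abatement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nh3iam)
```

## Scope and model chain

`nh3iam` is a desk-scale integrated assessment pipeline for agricultural
ammonia (NH3) abatement under two farming regimes: the current
smallholder-dominated regime, and a large-scale farming regime in which
crop parcels are consolidated and free-range livestock moves to
large-scale point-source farms. The chain is

1. **synthetic region** — a seeded gridded study region with the
   statistical structure the analysis assumes;
2. **inventory** — gridded, monthly, sectoral NH3 emissions from emission
   factors times activity, with Monte Carlo uncertainty;
3. **farm-structure transition** — parcel consolidation under a terrain
   constraint, fertilizer-intensity decline with farm size, and
   within-province reallocation of free-range livestock;
4. **abatement scenarios** — technology measures through an
   adoption-weighted mitigation-efficiency rule, and demand-side
   food-loss-and-waste measures as activity scaling;
5. **air quality** — a reduced-form inorganic-aerosol equilibrium giving
   the non-linear PM2.5 response to NH3;
6. **health** — GEMM hazard-ratio curves and attributable mortality;
7. **economics** — annualized costs, ledgers, net benefits and
   benefit–cost ratios.

Everything is driven from one seed through named substreams, so a full run
is reproducible file-for-file.

## The synthetic region

The generator (`generate_region()`) replaces all external datasets — real
gridded inventories, digital elevation models, farm surveys and
point-of-interest registries — with a self-consistent fixture. The default
configuration describes a China-like region at coarse desk scale: a
30 × 30 grid of 1 Mha cells (9 Mkm²), 134.9 Mha of cropland at a mean N
application rate of 197.8 kg N ha⁻¹, 1.6 billion pig units of livestock
(62.5% free-range), a population of 1.39 billion, and 30 provinces of
which six are "pilot" provinces covering 20% of the area.

Design choices worth noting:

* **Spatial structure.** Hotspots are produced by box-blurred white noise
  (a cheap autocorrelated random field) plus a latent boost inside pilot
  provinces. Real geography is deliberately not reproduced; what the
  downstream analysis needs is only that emission hotspots exist, that
  they co-locate with population, and that the pilot provinces carry a
  majority (~55%) of national emissions on ~20% of the area.
* **Exact national totals.** Cropland, pig units, population and the
  cropland-weighted mean N rate are rescaled to their configured totals,
  so national accounting identities hold exactly rather than in
  expectation.
* **Slope.** Cell slopes are quantile-mapped from a log-normal
  distribution against cumulative cropland weights, so that a configured
  share of *cropland* (default 22.7%) lies above the 6° mechanization
  threshold, to within half a cell's weight.
* **Parcel histograms.** Within-cell parcel sizes follow a log-normal
  whose cell-level location parameter varies spatially; a single global
  shift is solved numerically so the national share of cropland mass in
  parcels under 2 ha matches the configured 80.8%. Bin edges
  (0, 0.5, 1, 2, 5, 10, 50 ha) place the 2-ha large-scale threshold on an
  edge, avoiding within-bin interpolation. Histograms store mass (ha) per
  bin; parcel counts are mass over bin midpoint.
* **Meteorology.** Monthly temperature is a sinusoid peaking in July with
  a north–south gradient (grid row 0 is the north-west corner); daily
  series, used only for polluted-day counting, are AR(1) log-deviations
  around monthly means.

What the fixture does *not* emulate: real administrative boundaries,
land-cover detail, survey-based farm-size estimation, or any correlation
between terrain and parcel size. Passing tests therefore demonstrate the
internal consistency of the method chain under realistic *structure*, not
agreement with any real region's data.

## Inventory

Emissions are emission factor × activity with an N→NH3 mass conversion of
17/14. The fertilizer volatilization fraction (0.151) and the total
livestock volatilization fraction of excreted manure N (0.422, at
7.2 kg N per pig unit per year) are calibration constants derived in
`default_emission_factors()` from the national baseline anchors
(12.8 Tg yr⁻¹ total; 5.9 Tg livestock, 4.9 Tg fertilizer, 2.0 Tg
non-agricultural remainder), so the default region reproduces those totals
and the 46.1%/38.2% sector shares identically. The split of the livestock
fraction across manure stages (housing/storage/spreading for confined
farms; spreading/grazing for free-range) is an assumption — no published
per-stage values are used — and both farm classes volatilize the same
total fraction, which makes the baseline national total invariant to the
class mix.

Monthly allocation multiplies base weights by `exp(s·T)` (s = 0.045 per
°C, chosen so summer-quarter emissions exceed winter-quarter emissions by
roughly the observed factor of ~2.6) and renormalizes. The
non-agricultural sector is population-proportional and seasonally flat.

Monte Carlo uncertainty perturbs each factor group (fertilizer EF,
livestock stage fractions, other) with independent median-1 log-normals
(geometric SDs 1.25/1.18/1.15) and reports empirical 5th/95th percentiles
of the national total. Correlation between factors is not modelled — it is
not identifiable from the anchors used here. Because perturbations act
multiplicatively on sector totals, draws do not re-run the gridded
inventory; 1,000 draws are the default.

## Farm-structure transition

Three rules, applied to the masked provinces (`regime = "pilot"` or
`"all"`):

* **Consolidation** merges all sub-2-ha parcel mass into the 2–5 ha bin in
  cells with slope ≤ 6°; steeper cells are untouched. Cropland is
  conserved exactly.
* **N-rate decline** follows a power law in the mean parcel size,
  `rate' = rate × (size'/size)^elasticity`, floored at 50 kg N ha⁻¹. The
  default elasticity (−0.26) is calibrated so the national mean rate falls
  by ≈31% under nationwide consolidation, given the default parcel
  histograms and the 22.7% of cropland excluded by terrain. A single
  power law stands in for survey-based statistical relationships between
  farm size and fertilizer intensity.
* **Livestock reallocation** moves free-range pig units onto the
  province's large-scale farms proportionally to existing capacity,
  keeping a configurable residual free-range share (11.5% of free-range
  units, i.e. 7.2% of the total, matching the post-transition large-scale
  share of 92.8%). Provinces without a large farm get one new point
  source at the cell with the largest free-range pool. Pig units are
  conserved exactly per province; head vectors are scaled species-wise so
  no artificial species conversion occurs.

Pig-unit conversion factors are 1 (swine), 10 (dairy cattle), 5 (beef
cattle), 1/3 (sheep/goats), 1/15 (layer poultry) and 1/60 (broiler
poultry) pig units per head. Large-scale class thresholds (e.g. >500 pigs,
>100 dairy cattle) are configuration; other species default to the
pig-unit equivalent of 500 pig units.

## Abatement scenarios

The emission remaining after a technology measure is
`E_r = (1 − adoption)·E + adoption·E·(1 − η) = E·(1 − adoption·η)`,
with η the measure's mitigation efficiency. Stacked technologies combine
multiplicatively, `η_comb = 1 − Π(1 − η_i)` — a survival-style rule chosen
because the alternative (summing) can exceed 1; combined reductions under
this rule are slightly below the sum of the per-measure rows, and the
package makes no attempt to reproduce any stream-overlap accounting
beyond it.

Adoption rates are farm-class-specific (crop: 22.2% smallholder / 43.8%
large-scale; livestock: 19.6% / 39.1%) and are resolved per cell from the
(possibly transitioned) farm structure, so the structural transition
raises effective adoption wherever it raises the large-scale share — this
coupling is the central mechanism of the assessment.

Per-measure efficiencies are calibration constants: each η is solved in
`default_measure_catalog()` so that the measure alone, under the
current-regime class mix, yields its reference national reduction (5.3%,
2.7%, 4.4% for the three fertilizer technologies; 2.2%, 9.7% for the two
livestock technologies). Demand-side measures (reduced meat, staple, and
fruit/vegetable loss and waste) scale sector activity directly with
adoption ≡ 1; their waste fractions are solved the same way from 10.6%,
0.8% and 1.3% reference reductions.

The five shipped scenarios are TECH (technologies only), RFLW
(demand-side only), NM (both), NMLF-PILOT (transition in pilot provinces,
N management nationwide) and NMLF-ALL (transition nationwide). On the
default region the national reductions order
RFLW < TECH < NM < NMLF-PILOT < NMLF-ALL (≈12.7, 18.3, 28.2, 37.5,
42.5%). The combined values are not expected to match any external
reference exactly — the multiplicative combination rule and the synthetic
region both differ from the data-rich original setting — but the ordering,
the per-measure rows and the regime contrast are preserved.

For the NMLF scenarios the transition *relocates* livestock emissions
between cells; receiving cells can therefore exceed their baseline
emission locally even though provincial and national totals never do. The
cell-wise bound `0 ≤ E_r ≤ E` holds unconditionally for the
fixed-structure scenarios (TECH, RFLW, NM).

## Air quality

A one-box steady state per cell and month stands in for a chemical
transport model: local NH3 concentration is emission flux divided by an
effective ventilation velocity (0.01 m s⁻¹, i.e. ~μg m⁻³ per
0.01 μg m⁻² s⁻¹ of flux), plus 0.3 times the regional mean. The
concentration feeds an inorganic-aerosol equilibrium:

* NH3 first neutralizes sulfate, up to 2 mol NH4 per mol SO4 (bisulfate
  when ammonia is short); sulfate is non-volatile.
* Remaining NH3 and HNO3 form NH4NO3 while their molar product exceeds a
  dissociation constant with `ln Kp(ppb²) = 118.87 − 24084/T −
  6.025·ln T`, reduced linearly above a deliquescence RH of 0.62 (floored
  at 5%). The smaller root of the equilibrium quadratic is taken, clamped
  to the physical range.

This preserves the regime distinction that drives every headline result:
in NH3-rich cells the response of PM2.5 to marginal NH3 cuts is nearly
flat; once cuts push a cell below the neutralization demand
(2·SO4 + NO3, in moles), the response steepens to ≈80/17 μg PM per μg
NH3. Total N and total nitrate are conserved to 1e-9 relative. Sulfate,
total nitrate and non-inorganic PM2.5 are fixed fields (8, 12 and
15 μg m⁻³ scaled by a population-based pollution weight) held constant
across scenarios; SOA, dust, transport and NH3 re-volatilization after
deposition are out of scope.

Polluted days use daily PM series built from monthly means times the
fixture's shared mean-one log-normal daily factors, with a strict
`> 150 μg m⁻³` exceedance.

The sub-grid experiment splits one ~2,500 km² coarse cell into 100 5-km
boxes and concentrates the livestock emission into k boxes. NH3 above a
local saturation (25 μg m⁻³) deposits with fraction `vd/(vd + dilution)`
of the excess before regional mixing; the surviving mean feeds the
equilibrium. The underestimation of the coarse-cell mean PM2.5 relative
to the uniform case is zero at k = 100 and at vd = 0, grows monotonically
as k falls, and reaches ≈11% at k = 1 under the defaults — the curve is
validated by shape, not by any specific value, since the original box
model's parameterization is not public.

## Health

GEMM hazard ratios
`HR(z) = exp(θ·log(z/α + 1)/(1 + exp(−(z − μ)/ν)))`, `z = max(0, PM −
2.4)`, for COPD, lung cancer, ischemic heart disease and stroke, with
all-age parameter sets following the published GEMM fits. Attributable
deaths per cell and cause are `population × rate × (1 − 1/HR)`; avoided
deaths are differences of attributable deaths against the baseline
exposure. Age-resolved parameters are not used — the synthetic region has
no age structure — and population and baseline rates (synthetic,
China-like magnitudes) are held fixed across scenarios. Uncertainty in θ
is not propagated by default.

## Economics

Annualized cost is `I·r(1+r)^lt/((1+r)^lt − 1) + FVO`; below r = 1e-9 the
analytic limit `I/lt + FVO` is used (the factor is continuous there to
first order in r). The scenario ledgers ship a mid-level line-item
catalog as reference data (costs, private benefits, GHG and "other"
societal items — the latter negative, since NH3 cuts can worsen
acid-rain-related damages); the human-health line is either taken from
the catalog or recomputed as avoided deaths × US$250,000. Net benefit is
`B_private + B_societal − costs` exactly, before any report rounding;
benefit–cost ratios are rounded half-up to two decimals in reports. RFLW
has *absent* (not zero) costs — demand-side cost quantification is out of
scope — so its ratio is undefined and printed as "—". Low/high parameter
levels are accepted through the catalog interface but only the mid level
ships with anchored values.

## Numerical choices and problem sizes

* All randomness flows from one seed via named substreams
  (`substream_seed`), so stages are independently reproducible and the
  whole pipeline is byte-deterministic.
* The default grid is 30 × 30; the test suite uses 8 × 8 regions with
  totals scaled to the grid's share of the default area, keeping per-cell
  densities (and hence all regime thresholds) unchanged. A full default
  pipeline run takes a few seconds on one core.
* Monte Carlo uses 1,000 draws by default; the log-normal quantile
  validation uses 10,000 draws on a single-factor toy inventory.
* Degenerate inputs: empty regions write valid empty fixtures; empty
  measure lists reduce nothing; zero-capacity provinces receive a seeded
  farm point during reallocation (or error if disallowed); the
  equilibrium clamps nitrate formation to `[0, min(NH3', HNO3)]`.

## Known limitations

The reduced-form air-quality model has no transport, so inter-regional
influence enters only through one background term; control efficiencies
and avoided-death totals are therefore indicative, not predictive. The
livestock stage split and the demand-side waste fractions are calibrated
or assumed, not measured. The generator's hotspot structure is
statistically, not geographically, realistic. The health module collapses
age structure. None of these affect the package's accounting identities,
conservation laws, or the regime ordering of scenario outcomes, which is
what the test suite pins down.
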