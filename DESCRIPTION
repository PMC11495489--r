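Package: nh3iam
Title: Integrated Assessment of Agricultural Ammonia Abatement Under
    Farm-Structure Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale integrated assessment pipeline for agricultural
    ammonia (NH3) abatement. Generates seeded synthetic study regions with
    cropland parcel-size structure, terrain slope, livestock point sources
    and meteorology; computes gridded seasonal sectoral NH3 emission
    inventories with Monte Carlo uncertainty; models the smallholder to
    large-scale farming transition (parcel consolidation under terrain
    constraints, fertilizer-rate decline with farm size, livestock
    reallocation); builds technology and demand-side abatement scenarios;
    propagates emissions through a reduced-form inorganic aerosol
    equilibrium to PM2.5; estimates PM2.5-attributable premature mortality
    with the GEMM hazard-ratio model; and closes with annualized
    cost-benefit accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
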