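#' Write a region fixture to disk
#'
#' Serializes the fixture as plain CSV (`cells.csv`, `farms.csv`,
#' `monthly_met.csv`, optionally `daily_met.csv`), a NetCDF file `fields.nc`
#' holding the gridded fields on named dimensions (`row`, `col`, `month`),
#' and `config.yml`. The file set round-trips losslessly through
#' [read_fixture()] (CSV doubles are written with shortest-round-trip
#' formatting).
#'
#' @param fixture An `nh3_region` object.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(fixture, directory) {
  stopifnot(inherits(fixture, "nh3_region"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2) != 0) {
    stop("cannot write fixture: directory `", directory, "` is not writable",
         call. = FALSE)
  }
  files <- character()
  wr <- function(df, name) {
    path <- file.path(directory, name)
    readr::write_csv(df, path, progress = FALSE)
    path
  }
  files <- c(files, wr(fixture$cells, "cells.csv"),
             wr(fixture$farms, "farms.csv"),
             wr(fixture$monthly_met, "monthly_met.csv"))
  if (!is.null(fixture$daily_met)) {
    files <- c(files, wr(fixture$daily_met, "daily_met.csv"))
  }
  cfg <- fixture$config
  yaml::write_yaml(unclass(cfg), file.path(directory, "config.yml"))
  files <- c(files, file.path(directory, "config.yml"))
  if (nrow(fixture$cells) > 0) {
    files <- c(files, write_fields_nc(fixture, file.path(directory, "fields.nc")))
  }
  invisible(files)
}

# gridded cell fields + monthly met as NetCDF with named dims (row, col, month)
write_fields_nc <- function(fixture, path) {
  cells <- fixture$cells
  nr <- fixture$config$n_rows; nc_ <- fixture$config$n_cols
  dim_row <- ncdf4::ncdim_def("row", "index", 0:(nr - 1))
  dim_col <- ncdf4::ncdim_def("col", "index", 0:(nc_ - 1))
  dim_month <- ncdf4::ncdim_def("month", "month", 1:12)
  grid_var <- function(name, units) {
    ncdf4::ncvar_def(name, units, list(dim_col, dim_row), prec = "double")
  }
  vars <- list(
    cropland = grid_var("cropland", "ha"),
    slope = grid_var("slope", "degrees"),
    n_rate = grid_var("n_rate", "kg N/ha"),
    population = grid_var("population", "persons"),
    temp = ncdf4::ncvar_def("temp", "degC", list(dim_col, dim_row, dim_month),
                            prec = "double"),
    rh = ncdf4::ncvar_def("rh", "fraction", list(dim_col, dim_row, dim_month),
                          prec = "double")
  )
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  as_grid <- function(v) matrix(v, nrow = nc_, ncol = nr)  # col-fastest layout
  ncdf4::ncvar_put(nc, vars$cropland, as_grid(cells$cropland_ha))
  ncdf4::ncvar_put(nc, vars$slope, as_grid(cells$slope_deg))
  ncdf4::ncvar_put(nc, vars$n_rate, as_grid(cells$n_rate))
  ncdf4::ncvar_put(nc, vars$population, as_grid(cells$population))
  met <- fixture$monthly_met[order(fixture$monthly_met$month,
                                   fixture$monthly_met$cell_id), ]
  arr_t <- array(met$temp_c, dim = c(nc_, nr, 12))
  arr_rh <- array(met$rh, dim = c(nc_, nr, 12))
  ncdf4::ncvar_put(nc, vars$temp, arr_t)
  ncdf4::ncvar_put(nc, vars$rh, arr_rh)
  path
}

#' Read a region fixture written by [write_fixture()]
#'
#' @param directory Directory containing the fixture files.
#' @return An `nh3_region` object.
#' @export
read_fixture <- function(directory) {
  p <- function(name) file.path(directory, name)
  if (!file.exists(p("cells.csv"))) {
    stop("no fixture found in `", directory, "`", call. = FALSE)
  }
  cells <- readr::read_csv(p("cells.csv"), show_col_types = FALSE,
                           progress = FALSE)
  farms <- readr::read_csv(p("farms.csv"), show_col_types = FALSE,
                           progress = FALSE)
  monthly_met <- readr::read_csv(p("monthly_met.csv"), show_col_types = FALSE,
                                 progress = FALSE)
  daily_met <- if (file.exists(p("daily_met.csv"))) {
    readr::read_csv(p("daily_met.csv"), show_col_types = FALSE, progress = FALSE)
  } else NULL
  cfg <- yaml::read_yaml(p("config.yml"))
  cfg$baseline_mortality <- unlist(cfg$baseline_mortality)
  cfg$livestock$species_share <- unlist(cfg$livestock$species_share)
  class(cfg) <- "nh3_region_config"
  if (nrow(farms) == 0) farms <- empty_farms()
  structure(list(cells = cells, farms = farms, monthly_met = monthly_met,
                 daily_met = daily_met, config = cfg),
            class = "nh3_region")
}
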