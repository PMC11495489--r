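#' @importFrom rlang .data
#' @importFrom stats quantile rnorm rlnorm runif rpois rgamma plogis qlnorm
#'   pnorm qnorm setNames
#' @importFrom utils head tail
NULL

# Internal assertion helpers -------------------------------------------------

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

abort_domain <- function(msg) {
  stop(msg, call. = FALSE)
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_domain(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_domain(sprintf("`%s` must be finite and >= 0", name))
  }
  invisible(x)
}

# Named random substreams ----------------------------------------------------
# All stage-level randomness flows from one top-level seed; each stage draws
# from an offset derived from its name so stages can be re-run independently.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) + 1009 * h) %% .Machine$integer.max)
}

# Spatial smoothing ----------------------------------------------------------
# Repeated box-blur of white noise on a grid; cheap stand-in for a Gaussian
# random field, giving the hotspot structure the analysis assumes.
smooth_field <- function(n_rows, n_cols, passes = 3, radius = 2) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  for (p in seq_len(passes)) {
    acc <- matrix(0, n_rows, n_cols)
    cnt <- matrix(0, n_rows, n_cols)
    for (dr in -radius:radius) {
      for (dc in -radius:radius) {
        rs <- max(1, 1 + dr):min(n_rows, n_rows + dr)
        rt <- max(1, 1 - dr):min(n_rows, n_rows - dr)
        cs <- max(1, 1 + dc):min(n_cols, n_cols + dc)
        ct <- max(1, 1 - dc):min(n_cols, n_cols - dc)
        acc[rt, ct] <- acc[rt, ct] + z[rs, cs]
        cnt[rt, ct] <- cnt[rt, ct] + 1
      }
    }
    z <- acc / cnt
  }
  as.vector(z / sd(z))
}

# AR(1) series ---------------------------------------------------------------
ar1_series <- function(n, rho, sd_innov) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_innov / sqrt(1 - rho^2))
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + rnorm(1, 0, sd_innov)
  x
}

# Month lengths (non-leap year), used to convert monthly masses to fluxes.
month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# Seasonal quarter masks (northern hemisphere)
summer_months <- c(6, 7, 8)
winter_months <- c(12, 1, 2)

#' NH3-N to NH3 mass conversion factor (17/14)
#'
#' Molecular weight of NH3 over atomic weight of N; converts a nitrogen mass
#' volatilized as ammonia into the corresponding ammonia mass.
#' @keywords internal
N_TO_NH3 <- 17 / 14
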