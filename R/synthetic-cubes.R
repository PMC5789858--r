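#' Double-logistic seasonal greenness curve
#'
#' The canonical seasonal NDVI model: a winter background plus an amplitude
#' modulated by a rising and a falling logistic,
#' `winter + amplitude * (1/(1+exp(-k_sos*(t-sos))) - 1/(1+exp(-k_eos*(t-eos))))`.
#' The inflection points `sos` and `eos` are the start and end of season by
#' construction, where the curve passes half amplitude with maximum slope.
#'
#' @param t day of year (numeric vector)
#' @param winter background NDVI
#' @param amplitude seasonal amplitude
#' @param sos,eos inflection days of year
#' @param k_sos,k_eos logistic slopes (1/day)
#' @return NDVI values at `t`
#' @export
#' @examples
#' double_logistic(120, 0.1, 0.6, sos = 120, eos = 280) # = 0.1 + 0.3
double_logistic <- function(t, winter, amplitude, sos, eos,
                            k_sos = 0.15, k_eos = 0.15) {
  winter + amplitude * (stats::plogis(k_sos * (t - sos)) -
                          stats::plogis(k_eos * (t - eos)))
}

# Nominal mid-composite DOYs for 24 bimonthly composites in a 365-day year.
composite_midpoints <- function() {
  round_half_up((seq_len(24L) - 0.5) * DAYS_PER_YEAR / 24)
}

#' Generate a synthetic bimonthly NDVI cube
#'
#' For every pixel and year the noiseless signal is a double-logistic curve
#' whose inflection points follow the truth grid's baseline dates plus linear
#' trends; independent Gaussian composite noise is added and values are
#' clipped to the physical NDVI range \[-0.2, 1\]. Each year carries exactly
#' 24 composites at fixed nominal mid-composite days.
#'
#' @param truth an `fp_truth` grid from [gen_truth()]
#' @param years contiguous calendar years
#' @param noise_sd per-composite Gaussian noise sd (NDVI units)
#' @param seed integer seed
#' @param k_sos,k_eos logistic slopes of the truth curve (1/day)
#' @return `fp_ndvi_cube`: values array with dimensions
#'   (composite, lat, lon, year), the composite mid-days, axes, and the
#'   originating truth grid (for parameter-recovery tests)
#' @export
gen_ndvi <- function(truth, years, noise_sd = 0.02, seed = 0L,
                     k_sos = 0.15, k_eos = 0.15) {
  stopifnot(inherits(truth, "fp_truth"))
  years <- assert_years_contiguous(years)
  n_lat <- length(truth$lat); n_lon <- length(truth$lon)
  n_year <- length(years)
  doys <- composite_midpoints()
  values <- array(NA_real_, dim = c(24L, n_lat, n_lon, n_year))
  for (i in seq_len(n_year)) {
    ph <- truth_phenology(truth, i - 1L)
    for (ci in seq_len(24L)) {
      values[ci, , , i] <- double_logistic(
        doys[ci], truth$ndvi_winter, truth$ndvi_amplitude,
        ph$sos, ph$eos, k_sos, k_eos
      )
    }
  }
  if (noise_sd > 0) {
    values <- values + withr::with_seed(
      as.integer(seed), rnorm(length(values), sd = noise_sd)
    )
  }
  values <- pmin(pmax(values, -0.2), 1.0)
  structure(
    list(values = values, years = years, composite_doy = doys,
         lat = truth$lat, lon = truth$lon, truth = truth,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "fp_ndvi_cube"
  )
}

#' @export
print.fp_ndvi_cube <- function(x, ...) {
  cat("<fp_ndvi_cube> ", length(x$lat), " x ", length(x$lon), " pixels, ",
      length(x$years), " years (", min(x$years), "-", max(x$years),
      "), 24 composites/yr, noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic sub-daily minimum-temperature cube
#'
#' Per pixel the signal is an annual mean plus a linear warming trend, minus
#' a seasonal cosine (coldest near `doy_cold_peak`, mid-January by default),
#' minus a deterministic diurnal cosine whose coldest sample falls at 06:00,
#' plus AR(1) day-to-day weather noise shared by all sub-daily samples of a
#' day. The calendar is a fixed 365-day year.
#'
#' @param truth an `fp_truth` grid
#' @param years contiguous calendar years
#' @param timestep_hours sampling interval, 3 or 6 hours
#' @param seed integer seed
#' @param doy_cold_peak day of year of the coldest point of the seasonal
#'   cycle (default 15)
#' @return `fp_tmin_cube`: values array with dimensions
#'   (sample-of-day, doy, year, lat, lon) in degrees C, plus axes and the
#'   originating truth grid
#' @export
gen_tmin <- function(truth, years, timestep_hours = 3L, seed = 0L,
                     doy_cold_peak = 15) {
  stopifnot(inherits(truth, "fp_truth"))
  years <- assert_years_contiguous(years)
  if (!timestep_hours %in% c(3L, 6L)) {
    stop("`timestep_hours` must be 3 or 6", call. = FALSE)
  }
  n_lat <- length(truth$lat); n_lon <- length(truth$lon)
  n_year <- length(years)
  spd <- as.integer(24L / timestep_hours)
  hours <- seq(0, 24 - timestep_hours, by = timestep_hours)
  n_days <- DAYS_PER_YEAR * n_year
  seasonal <- -cos(2 * pi * (seq_len(DAYS_PER_YEAR) - doy_cold_peak) / 365.25)
  values <- array(NA_real_, dim = c(spd, DAYS_PER_YEAR, n_year, n_lat, n_lon))
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(n_lon)) {
      for (i in seq_len(n_lat)) {
        base_daily <- as.vector(outer(
          truth$tmin_seasonal_amplitude[i, j] * seasonal,
          truth$tmin_annual_mean[i, j] +
            truth$tmin_trend[i, j] * (seq_len(n_year) - 1L),
          `+`
        ))
        sdp <- truth$tmin_noise_sd[i, j]
        phi <- truth$tmin_ar1[i, j]
        if (sdp > 0) {
          init <- rnorm(1, sd = sdp)
          innov <- rnorm(n_days, sd = sdp * sqrt(1 - phi^2))
          noise <- as.numeric(
            stats::filter(innov, phi, method = "recursive", init = init)
          )
        } else {
          noise <- numeric(n_days)
        }
        diurnal <- -truth$tmin_diurnal_amplitude[i, j] *
          cos(2 * pi * (hours - 6) / 24)
        values[, , , i, j] <- rep(base_daily + noise, each = spd) + diurnal
      }
    }
  })
  structure(
    list(values = values, timestep_hours = as.integer(timestep_hours),
         hours = hours, years = years, lat = truth$lat, lon = truth$lon,
         resolution = truth$resolution, truth = truth, units = "degC",
         seed = as.integer(seed)),
    class = "fp_tmin_cube"
  )
}

#' @export
print.fp_tmin_cube <- function(x, ...) {
  cat("<fp_tmin_cube> ", length(x$lat), " x ", length(x$lon), " pixels, ",
      length(x$years), " years, ", x$timestep_hours, "-h step (",
      dim(x$values)[1], " samples/day), units ", x$units, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic site-level phenology table
#'
#' Emulates a network of in-situ observers: each site sits at a random grid
#' pixel and reports leaf-unfolding and leaf-senescence days of year equal to
#' the pixel's true season start/end plus Gaussian observation noise, rounded
#' to integer DOY, with whole site-years missing at random.
#'
#' @param truth an `fp_truth` grid
#' @param n_sites number of sites (>= 1)
#' @param years contiguous calendar years
#' @param obs_noise_sd observation noise sd (days)
#' @param missing_rate probability in \[0, 1) that a site-year is unreported
#' @param seed integer seed
#' @return tibble with columns site_id, lat, lon, year, unfold_doy,
#'   senesce_doy
#' @export
gen_insitu <- function(truth, n_sites, years, obs_noise_sd = 3,
                       missing_rate = 0.1, seed = 0L) {
  stopifnot(inherits(truth, "fp_truth"))
  years <- assert_years_contiguous(years)
  if (n_sites < 1) stop("`n_sites` must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  n_lat <- length(truth$lat); n_lon <- length(truth$lon)
  withr::with_seed(as.integer(seed), {
    i_lat <- sample.int(n_lat, n_sites, replace = TRUE)
    i_lon <- sample.int(n_lon, n_sites, replace = TRUE)
    tab <- tidyr::expand_grid(
      site = seq_len(n_sites), year = years
    )
    yo <- tab$year - years[1]
    sos_true <- truth$sos0[cbind(i_lat[tab$site], i_lon[tab$site])] +
      truth$sos_trend[cbind(i_lat[tab$site], i_lon[tab$site])] * yo
    eos_true <- truth$eos0[cbind(i_lat[tab$site], i_lon[tab$site])] +
      truth$eos_trend[cbind(i_lat[tab$site], i_lon[tab$site])] * yo
    out <- tibble::tibble(
      site_id = sprintf("S%04d", tab$site),
      lat = truth$lat[i_lat[tab$site]],
      lon = truth$lon[i_lon[tab$site]],
      year = tab$year,
      unfold_doy = round_half_up(sos_true + rnorm(nrow(tab), sd = obs_noise_sd)),
      senesce_doy = round_half_up(eos_true + rnorm(nrow(tab), sd = obs_noise_sd))
    )
    if (missing_rate > 0) {
      out <- out[runif(nrow(out)) >= missing_rate, ]
    }
    out
  })
}
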