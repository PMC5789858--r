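#' Default parameter ranges for the synthetic truth grid
#'
#' The defaults describe a mid-to-high-latitude Northern-Hemisphere world:
#' growing seasons starting in late April/May and ending in September/October,
#' moderate greenness amplitude over a low winter background, a strong
#' seasonal temperature cycle with a few degrees of diurnal range,
#' autocorrelated synoptic weather noise, an advancing start of season,
#' a delaying end of season, and a warming trend of a few hundredths of a
#' degree per year (about 0.7 degrees C between a 1980s and a 2000s decade).
#'
#' Each element is a length-2 `c(min, max)` range; a degenerate range
#' (`min == max`) pins the field to a constant.
#'
#' @param ... named ranges overriding individual defaults, e.g.
#'   `truth_ranges(sos_trend = c(-0.4, -0.4), tmin_trend = c(0, 0))`.
#' @return named list of ranges understood by [gen_truth()]
#' @export
#' @examples
#' truth_ranges(tmin_trend = c(0, 0))$tmin_trend
truth_ranges <- function(...) {
  defaults <- list(
    sos0 = c(110, 145),               # baseline start of season, DOY
    eos0 = c(255, 295),               # baseline end of season, DOY
    sos_trend = c(-0.4, -0.1),        # days/yr, negative = advancing
    eos_trend = c(0.05, 0.25),        # days/yr
    ndvi_winter = c(0.05, 0.15),      # background NDVI
    ndvi_amplitude = c(0.40, 0.60),   # seasonal NDVI amplitude
    tmin_annual_mean = c(-2, 6),      # degC
    tmin_seasonal_amplitude = c(12, 18), # degC
    tmin_diurnal_amplitude = c(2, 4), # degC
    tmin_trend = c(0.02, 0.05),       # degC/yr
    tmin_ar1 = c(0.6, 0.8),           # lag-1 autocorrelation of daily noise
    tmin_noise_sd = c(2.5, 4)         # degC, stationary sd of daily noise
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown truth range(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  defaults
}

validate_truth_ranges <- function(ranges) {
  needed <- names(truth_ranges())
  missing <- setdiff(needed, names(ranges))
  if (length(missing) > 0) {
    stop("ranges missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop("range `", nm, "` must be a finite c(min, max) pair", call. = FALSE)
    }
  }
  if (ranges$sos0[1] <= 0) {
    stop("sos0 range must be strictly positive", call. = FALSE)
  }
  if (ranges$eos0[2] > 366) {
    stop("eos0 range must not exceed DOY 366", call. = FALSE)
  }
  if (ranges$eos0[1] - ranges$sos0[2] < 30) {
    stop("eos0 must exceed sos0 by at least 30 days for every pixel; ",
         "min(eos0) - max(sos0) = ", ranges$eos0[1] - ranges$sos0[2],
         call. = FALSE)
  }
  if (ranges$ndvi_winter[2] + ranges$ndvi_amplitude[2] > 1) {
    stop("ndvi_winter + ndvi_amplitude may exceed 1.0 under these ranges",
         call. = FALSE)
  }
  if (ranges$tmin_ar1[1] < 0 || ranges$tmin_ar1[2] >= 1) {
    stop("tmin_ar1 must lie in [0, 1)", call. = FALSE)
  }
  for (nm in c("ndvi_amplitude", "tmin_seasonal_amplitude",
               "tmin_diurnal_amplitude", "tmin_noise_sd")) {
    if (ranges[[nm]][1] < 0) {
      stop("range `", nm, "` must be non-negative", call. = FALSE)
    }
  }
  invisible(ranges)
}

#' Generate a synthetic truth grid
#'
#' Draws smoothly varying per-pixel truth fields (baseline phenology, trends,
#' NDVI curve parameters, minimum-temperature climate parameters) from which
#' NDVI and temperature cubes with known answers can be generated. Fields are
#' low-order random surfaces so that moving-window statistics downstream see
#' genuine spatial structure.
#'
#' @param n_lat,n_lon grid dimensions (cells)
#' @param ranges parameter ranges from [truth_ranges()]
#' @param seed integer seed; the result is a pure function of all arguments
#' @param lat_start northernmost cell-center latitude (degrees N); the grid
#'   extends southward in `resolution` steps
#' @param lon_start westernmost cell-center longitude (degrees E)
#' @param resolution grid spacing in degrees
#' @return an object of class `fp_truth`: latitude/longitude axes plus one
#'   `n_lat x n_lon` matrix per truth field
#' @export
#' @examples
#' tr <- gen_truth(4, 6, seed = 1)
#' dim(tr$sos0)
gen_truth <- function(n_lat, n_lon, ranges = truth_ranges(), seed = 0L,
                      lat_start = 70.25, lon_start = 0.25, resolution = 0.5) {
  if (n_lat < 1 || n_lon < 1) stop("grid must be at least 1 x 1", call. = FALSE)
  validate_truth_ranges(ranges)
  lat <- lat_start - resolution * (seq_len(n_lat) - 1L)
  lon <- lon_start + resolution * (seq_len(n_lon) - 1L)
  fields <- withr::with_seed(as.integer(seed), {
    lapply(ranges, function(r) surface_in_range(n_lat, n_lon, r))
  })
  out <- c(
    list(lat = lat, lon = lon, resolution = resolution, seed = as.integer(seed)),
    fields
  )
  class(out) <- "fp_truth"
  out
}

#' @export
print.fp_truth <- function(x, ...) {
  cat("<fp_truth> ", length(x$lat), " x ", length(x$lon),
      " grid at ", x$resolution, " deg; lat ",
      round(min(x$lat), 2), "..", round(max(x$lat), 2), " N\n", sep = "")
  cat("  SOS ", round(min(x$sos0)), "-", round(max(x$sos0)),
      ", EOS ", round(min(x$eos0)), "-", round(max(x$eos0)),
      " (DOY); Tmin trend ", signif(min(x$tmin_trend), 3), "..",
      signif(max(x$tmin_trend), 3), " degC/yr\n", sep = "")
  invisible(x)
}

# True phenology dates for a given year offset (years since record start);
# returns list of matrices. Used by generators and recovery tests.
truth_phenology <- function(truth, year_offset) {
  list(
    sos = truth$sos0 + truth$sos_trend * year_offset,
    eos = truth$eos0 + truth$eos_trend * year_offset
  )
}

#' True per-pixel, per-year phenology as a tibble
#'
#' Expands a truth grid into the same tabular layout that
#' [extract_phenology()] produces, for parameter-recovery comparisons and for
#' running the frost-counting stages directly on known phenology.
#'
#' @param truth an `fp_truth` grid
#' @param years calendar years
#' @param round should dates be rounded to integer DOY (the convention used
#'   for counting)? Default `TRUE`.
#' @return tibble with columns lat, lon, year, method ("truth"), sos, eos, gsl
#' @export
truth_phenology_grid <- function(truth, years, round = TRUE) {
  years <- assert_years_contiguous(years)
  px <- pixel_tibble(truth$lat, truth$lon)
  out <- purrr::map_dfr(seq_along(years), function(i) {
    ph <- truth_phenology(truth, i - 1L)
    tibble::tibble(
      lat = px$lat, lon = px$lon, year = years[i], method = "truth",
      sos = as.vector(ph$sos), eos = as.vector(ph$eos)
    )
  })
  if (round) {
    out$sos <- as.numeric(round_half_up(out$sos))
    out$eos <- as.numeric(round_half_up(out$eos))
  }
  out$gsl <- out$eos - out$sos
  out
}
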