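#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif sd cor pt qt complete.cases setNames
#' @importFrom utils head tail
NULL

# Fixed 365-day calendar used everywhere in the synthetic world.
DAYS_PER_YEAR <- 365L

# Summer solstice (22 June) in the fixed 365-day calendar.
SOLSTICE_DOY <- 173L

#' Round half up to the nearest integer
#'
#' Phenological dates are reported as integer day-of-year with ties rounded
#' away from zero-point-five upward (so 120.5 -> 121), unlike [round()]'s
#' banker's rounding.
#'
#' @param x numeric vector
#' @return integer vector, `NA` preserved
#' @keywords internal
round_half_up <- function(x) {
  out <- floor(x + 0.5)
  storage.mode(out) <- "integer"
  out
}

# cos-latitude area weights, normalised to sum to 1 over non-missing entries
cos_lat_weights <- function(lat, valid = NULL) {
  w <- cos(lat * pi / 180)
  if (!is.null(valid)) w[!valid] <- 0
  if (sum(w) <= 0) stop("no valid pixels to weight", call. = FALSE)
  w / sum(w)
}

# Low-order smooth random surface on [0, 1], used for spatially structured
# truth fields. A handful of random Fourier modes, rescaled to the unit
# interval; degenerates to 0.5 on a 1 x 1 grid or when the surface is flat.
random_surface <- function(n_lat, n_lon, n_modes = 3L) {
  u <- seq_len(n_lat) / max(n_lat, 1L)
  v <- seq_len(n_lon) / max(n_lon, 1L)
  s <- matrix(0, n_lat, n_lon)
  for (k in seq_len(n_modes)) {
    amp <- 1 / k
    s <- s + amp * outer(
      cos(2 * pi * (k * u + runif(1))),
      cos(2 * pi * (k * v + runif(1)))
    )
    s <- s + amp * outer(
      sin(2 * pi * (k * u + runif(1))),
      sin(2 * pi * (k * v + runif(1)))
    )
  }
  rng <- range(s)
  if (diff(rng) < .Machine$double.eps) {
    matrix(0.5, n_lat, n_lon)
  } else {
    (s - rng[1]) / diff(rng)
  }
}

# Map a value range onto a smooth surface; degenerate range gives a constant.
surface_in_range <- function(n_lat, n_lon, range) {
  if (range[1] == range[2]) {
    matrix(range[1], n_lat, n_lon)
  } else {
    range[1] + (range[2] - range[1]) * random_surface(n_lat, n_lon)
  }
}

assert_years_contiguous <- function(years) {
  if (length(years) == 0) stop("`years` must be non-empty", call. = FALSE)
  if (length(years) > 1 && any(diff(years) != 1)) {
    stop("`years` must be contiguous calendar years", call. = FALSE)
  }
  invisible(as.integer(years))
}

# Long pixel index helpers: arrays are (lat, lon, ...) with lat varying fastest.
pixel_tibble <- function(lat, lon) {
  lat_col <- rep(lat, times = length(lon))
  lon_col <- rep(lon, each = length(lat))
  tibble::tibble(lat = lat_col, lon = lon_col)
}
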