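#' Collapse a sub-daily minimum-temperature cube to daily minima
#'
#' A frost day is defined on the daily minimum, so the sub-daily samples of
#' each calendar day are reduced to their minimum first. Days must be
#' complete (every sample present).
#'
#' @param tmin an `fp_tmin_cube`
#' @return `fp_daily_tmin`: values array (doy, year, lat, lon) in degrees C
#' @export
daily_min <- function(tmin) {
  stopifnot(inherits(tmin, "fp_tmin_cube"))
  if (any(!is.finite(tmin$values))) {
    stop("sub-daily cube has missing samples; only complete days are supported",
         call. = FALSE)
  }
  dm <- dim(tmin$values)
  spd <- dm[1]
  m <- matrix(tmin$values, nrow = spd)
  daily <- do.call(pmin, lapply(seq_len(spd), function(r) m[r, ]))
  structure(
    list(values = array(daily, dim = dm[-1]), years = tmin$years,
         lat = tmin$lat, lon = tmin$lon, units = tmin$units,
         resolution = tmin$resolution %||% axis_resolution(tmin$lat, tmin$lon)),
    class = "fp_daily_tmin"
  )
}

#' @export
print.fp_daily_tmin <- function(x, ...) {
  cat("<fp_daily_tmin> ", length(x$lat), " x ", length(x$lon), " pixels, ",
      length(x$years), " years x ", DAYS_PER_YEAR, " days\n", sep = "")
  invisible(x)
}

#' Extract one pixel-year's daily minimum series
#'
#' @param daily an `fp_daily_tmin`
#' @param lat,lon cell-center coordinates (matched to the nearest cell
#'   within half a grid step)
#' @param year calendar year
#' @return numeric vector of 365 daily minima (degrees C)
#' @export
daily_series <- function(daily, lat, lon, year) {
  i <- match_axis(lat, daily$lat, daily$resolution)
  j <- match_axis(lon, daily$lon, daily$resolution)
  yi <- match(year, daily$years)
  if (is.na(i) || is.na(j)) stop("location outside the grid", call. = FALSE)
  if (is.na(yi)) stop("year ", year, " not in the cube", call. = FALSE)
  daily$values[, yi, i, j]
}

match_axis <- function(x, axis, res = NULL) {
  if (is.null(res)) {
    res <- if (length(axis) > 1) abs(axis[2] - axis[1]) else Inf
  }
  i <- which.min(abs(axis - x))
  if (abs(axis[i] - x) > res / 2 + 1e-9) NA_integer_ else i
}

# grid spacing inferred from the axes; 1 x 1 grids default to a half degree
axis_resolution <- function(lat, lon) {
  if (length(lat) > 1) abs(lat[2] - lat[1])
  else if (length(lon) > 1) abs(lon[2] - lon[1])
  else 0.5
}

#' Count frost days in a window of one daily series
#'
#' A frost day has daily minimum temperature strictly below 0 degrees C; a
#' day at exactly 0.0 is not frost. The window is the closed day interval
#' `[start_doy, end_doy]`. Missing window bounds give a missing count.
#'
#' @param daily_values numeric vector of 365 daily minima
#' @param start_doy,end_doy window bounds (1-based day of year)
#' @return integer count, or `NA` if a bound is missing
#' @export
#' @examples
#' v <- rep(5, 365); v[150:159] <- -1
#' count_frost_days(v, 145, 200)  # 10
count_frost_days <- function(daily_values, start_doy, end_doy) {
  if (is.na(start_doy) || is.na(end_doy)) return(NA_integer_)
  if (start_doy < 1 || end_doy > DAYS_PER_YEAR || start_doy > end_doy) {
    stop("window must satisfy 1 <= start_doy <= end_doy <= ", DAYS_PER_YEAR,
         call. = FALSE)
  }
  sum(daily_values[start_doy:end_doy] < 0)
}

# cutoff day for the spring/autumn split
split_cutoff <- function(sos, eos, cutoff_mode) {
  if (cutoff_mode == "solstice") rep(SOLSTICE_DOY, length(sos))
  else floor((sos + eos) / 2)
}

#' Split a window's frost count into spring and autumn
#'
#' Spring runs from season start to the cutoff (the summer solstice, day
#' 173 = 22 June in the fixed calendar, or the mid-season day); autumn from
#' the day after the cutoff to season end. The cutoff day itself belongs to
#' spring so that the two parts always sum to the full-season count. A
#' season that ends before the cutoff has an empty autumn; one that starts
#' after it has an empty spring.
#'
#' @param daily_values numeric vector of 365 daily minima
#' @param sos,eos season window (integer DOY)
#' @param cutoff_mode `"solstice"` or `"midseason"`
#' @return named integer vector `c(spr_fd = , fal_fd = )`
#' @export
split_counts <- function(daily_values, sos, eos,
                         cutoff_mode = c("solstice", "midseason")) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (is.na(sos) || is.na(eos)) {
    return(c(spr_fd = NA_integer_, fal_fd = NA_integer_))
  }
  if (sos >= eos) stop("season requires sos < eos", call. = FALSE)
  cutoff <- split_cutoff(sos, eos, cutoff_mode)
  if (sos > cutoff) {
    spr <- 0L
    fal <- count_frost_days(daily_values, sos, eos)
  } else {
    spr <- count_frost_days(daily_values, sos, min(cutoff, eos))
    fal <- if (cutoff >= eos) 0L else
      count_frost_days(daily_values, min(cutoff, eos) + 1L, eos)
  }
  c(spr_fd = spr, fal_fd = fal)
}

#' Frost-day timing histograms relative to the season edges
#'
#' Bins spring frost days by their offset from the season start
#' (`doy - sos` in \[0, 10), \[10, 20), ...) up to the cutoff, and autumn
#' frost days by their lead before the season end (`eos - doy`). Bin sums
#' equal the spring/autumn counts of [split_counts()].
#'
#' @inheritParams split_counts
#' @param bin_days bin width in days (default 10)
#' @return tibble with columns part ("spring"/"autumn"), bin_start (offset
#'   of the bin's first day), count
#' @export
timing_histograms <- function(daily_values, sos, eos,
                              cutoff_mode = c("solstice", "midseason"),
                              bin_days = 10L) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (is.na(sos) || is.na(eos)) {
    return(tibble::tibble(part = character(), bin_start = integer(),
                          count = integer()))
  }
  cutoff <- split_cutoff(sos, eos, cutoff_mode)
  frost_doy <- which(daily_values < 0)
  spring_days <- frost_doy[frost_doy >= sos & frost_doy <= min(cutoff, eos)]
  autumn_days <- if (cutoff >= eos) integer() else
    frost_doy[frost_doy > cutoff & frost_doy <= eos]
  bin_table <- function(offsets, span, part) {
    n_bins <- max(1L, ceiling((span + 1L) / bin_days))
    counts <- tabulate(offsets %/% bin_days + 1L, nbins = n_bins)
    tibble::tibble(part = part,
                   bin_start = (seq_len(n_bins) - 1L) * bin_days,
                   count = counts)
  }
  dplyr::bind_rows(
    bin_table(spring_days - sos, max(min(cutoff, eos) - sos, 0L), "spring"),
    bin_table(eos - autumn_days, max(eos - cutoff - 1L, 0L), "autumn")
  )
}

#' Count growing-season frost days for every pixel-year of a phenology table
#'
#' Vectorized counting over all pixels and years: days with minimum
#' temperature strictly below 0 degrees C inside the closed window
#' `[sos, eos]`, split into spring/autumn at the chosen cutoff. Rows with
#' missing phenology get missing counts.
#'
#' @param daily an `fp_daily_tmin`
#' @param phen phenology tibble (lat, lon, year, sos, eos; a `method`
#'   column, if present, is carried through)
#' @param cutoff_mode `"solstice"` (default) or `"midseason"`
#' @return tibble with columns lat, lon, year, (method,) sos, eos, gsfd,
#'   spr_fd, fal_fd
#' @export
#' @examples
#' tr <- gen_truth(2, 2, seed = 1)
#' tm <- gen_tmin(tr, 2000:2001, timestep_hours = 6, seed = 2)
#' ph <- truth_phenology_grid(tr, 2000:2001)
#' frost_counts(daily_min(tm), ph)
frost_counts <- function(daily, phen,
                         cutoff_mode = c("solstice", "midseason")) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(inherits(daily, "fp_daily_tmin"))
  dm <- dim(daily$values)
  # cumulative frost-day counts along the day axis, per (year, lat, lon)
  frost <- daily$values < 0
  cs <- array(apply(frost, c(2, 3, 4), cumsum), dim = dm)
  iy <- match(phen$year, daily$years)
  ilat <- vapply(phen$lat, match_axis, integer(1), axis = daily$lat,
                 res = daily$resolution)
  ilon <- vapply(phen$lon, match_axis, integer(1), axis = daily$lon,
                 res = daily$resolution)
  if (any(is.na(iy)) || any(is.na(ilat)) || any(is.na(ilon))) {
    stop("phenology table refers to years or cells outside the cube",
         call. = FALSE)
  }
  sos <- as.integer(phen$sos); eos <- as.integer(phen$eos)
  valid <- !is.na(sos) & !is.na(eos) & sos < eos
  count_window <- function(s, e) {
    # closed [s, e]; returns 0 for empty windows (s > e), NA where invalid
    out <- rep(NA_integer_, length(s))
    ok <- valid & !is.na(s) & !is.na(e)
    nonempty <- ok & s <= e
    idx_hi <- cbind(e[nonempty], iy[nonempty], ilat[nonempty], ilon[nonempty])
    hi <- cs[idx_hi]
    lo <- ifelse(s[nonempty] > 1L,
                 cs[cbind(pmax(s[nonempty] - 1L, 1L), iy[nonempty],
                          ilat[nonempty], ilon[nonempty])],
                 0)
    out[nonempty] <- as.integer(hi - lo)
    out[ok & s > e] <- 0L
    out
  }
  cutoff <- split_cutoff(sos, eos, cutoff_mode)
  spr_start <- ifelse(sos > cutoff, NA_integer_, sos)
  spr_end <- ifelse(sos > cutoff, NA_integer_, pmin(cutoff, eos))
  fal_start <- ifelse(sos > cutoff, sos, pmin(cutoff, eos) + 1L)
  fal_end <- eos
  spr <- count_window(spr_start, spr_end)
  spr[valid & sos > cutoff] <- 0L
  fal <- count_window(fal_start, fal_end)
  out <- tibble::tibble(
    lat = phen$lat, lon = phen$lon, year = phen$year,
    sos = phen$sos, eos = phen$eos,
    gsfd = spr + fal, spr_fd = spr, fal_fd = fal
  )
  if ("method" %in% names(phen)) {
    out <- dplyr::mutate(out, method = phen$method, .after = "year")
  }
  attr(out, "cutoff_mode") <- cutoff_mode
  out
}
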