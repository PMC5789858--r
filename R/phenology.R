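#' @name phenology
#' @title Threshold-based season dating from fitted NDVI curves
#' @description
#' Season dating follows the climatological-threshold scheme: the multi-year
#' mean composites are fitted once per pixel and method; the day of maximum
#' NDVI increase within the first half-year (day 1-182) defines the
#' climatological season start and the day of maximum decrease within the
#' second half (day 183-365) the season end; the fitted NDVI values at those
#' two dates become pixel thresholds; each individual year's fitted curve is
#' then dated by its first upward crossing of the start threshold and last
#' downward crossing of the end threshold. For the logistic models the
#' climatological dates are the fitted inflection parameters themselves.
NULL

# first upward crossing of thr by f within [lo, hi]; linear interpolation
first_up_crossing <- function(f, thr, lo, hi) {
  d <- lo:(hi - 1L)
  hit <- which(f[d] < thr & f[d + 1L] >= thr)
  if (length(hit) == 0) return(NA_real_)
  d0 <- d[hit[1]]
  d0 + (thr - f[d0]) / (f[d0 + 1L] - f[d0])
}

# last downward crossing of thr by f within [lo, hi]
last_down_crossing <- function(f, thr, lo, hi) {
  d <- lo:(hi - 1L)
  hit <- which(f[d] >= thr & f[d + 1L] < thr)
  if (length(hit) == 0) return(NA_real_)
  d0 <- d[hit[length(hit)]]
  d0 + (f[d0] - thr) / (f[d0] - f[d0 + 1L])
}

local_maxima <- function(f) {
  n <- length(f)
  if (n < 3) return(integer())
  which(f[2:(n - 1L)] > f[1:(n - 2L)] & f[2:(n - 1L)] >= f[3:n]) + 1L
}

#' Determine the season-window rule for a fitted annual curve
#'
#' Detects a double growing season (two local maxima of the fitted curve
#' separated by a trough of at least `trough_frac` of the curve amplitude)
#' and returns the day windows in which the start/end threshold crossings are
#' searched. For a unimodal curve this is the identity rule (first/second
#' half-year). With two complete seasons, the season start is taken from the
#' first season and the season end from the second; when the second season
#' has not ended by day 365 (its fall crosses into the next year), both dates
#' come from the first season.
#'
#' @param curve an `fp_curve`
#' @param eos_thresh NDVI threshold whose downward crossing defines the
#'   season end (used to decide whether the second season completes)
#' @param sos_thresh NDVI threshold for the season start; when given, a
#'   candidate season peak must exceed both thresholds to count as a season
#' @param trough_frac minimum trough depth as a fraction of curve amplitude
#' @param half_split last day of the "first half year" (default 182)
#' @return list with elements `bimodal`, `sos_window`, `eos_window`
#' @export
resolve_double_season <- function(curve, eos_thresh = NA_real_,
                                  sos_thresh = NA_real_,
                                  trough_frac = 0.1, half_split = 182L) {
  f <- curve$fitted
  unimodal <- list(bimodal = FALSE,
                   sos_window = c(1L, half_split),
                   eos_window = c(half_split + 1L, DAYS_PER_YEAR))
  if (any(!is.finite(f))) return(unimodal)
  peaks <- local_maxima(f)
  amp <- max(f) - min(f)
  if (amp <= 0) return(unimodal)
  # a season peak must be a substantial rise above the curve floor and above
  # the dating thresholds; this keeps boundary swings and side-lobes of
  # harmonic/polynomial reconstructions from being mistaken for a second
  # growing season
  floor_val <- min(f) + 0.25 * amp
  if (is.finite(sos_thresh)) floor_val <- max(floor_val, sos_thresh)
  if (is.finite(eos_thresh)) floor_val <- max(floor_val, eos_thresh)
  peaks <- peaks[f[peaks] > floor_val]
  if (length(peaks) < 2) return(unimodal)
  peaks <- peaks[order(f[peaks], decreasing = TRUE)]
  p <- sort(peaks[1:2])
  trough_val <- min(f[p[1]:p[2]])
  if (f[p[1]] - trough_val < trough_frac * amp ||
      f[p[2]] - trough_val < trough_frac * amp) {
    return(unimodal)
  }
  trough_at <- p[1] - 1L + which.min(f[p[1]:p[2]])
  second_complete <- is.finite(eos_thresh) &&
    !is.na(last_down_crossing(f, eos_thresh, p[2], DAYS_PER_YEAR))
  if (second_complete) {
    list(bimodal = TRUE, sos_window = c(1L, p[1]),
         eos_window = c(p[2], DAYS_PER_YEAR))
  } else {
    # second season ends next calendar year: use the first season only
    list(bimodal = TRUE, sos_window = c(1L, p[1]),
         eos_window = c(p[1], trough_at))
  }
}

#' Climatological season dates and NDVI thresholds from a mean-year curve
#'
#' For harmonic and polynomial fits the dates come from a discrete slope
#' scan of the fitted daily curve (maximum day-to-day increase in days
#' 1-182 for the start, maximum decrease in days 183-365 for the end; ties
#' resolved to the earliest day). For the logistic models they are the
#' models' own inflection-day parameters. The fitted NDVI at each date is
#' returned as the threshold used to date individual years.
#'
#' @param curve an `fp_curve` fitted to the multi-year mean composites
#' @param half_split last day of the first half-year (default 182)
#' @return list with `sos`, `eos` (integer DOY or `NA`), `sos_thresh`,
#'   `eos_thresh`
#' @export
climatological_dates <- function(curve, half_split = 182L) {
  miss <- list(sos = NA_integer_, eos = NA_integer_,
               sos_thresh = NA_real_, eos_thresh = NA_real_)
  d <- curve$diagnostics
  if (!isTRUE(d$converged) || isTRUE(d$non_seasonal)) return(miss)
  f <- curve$fitted
  if (any(!is.finite(f))) return(miss)
  if (!is.null(curve$params) &&
      all(c("S", "E") %in% names(curve$params))) {
    sos <- round_half_up(curve$params[["S"]])
    eos <- round_half_up(curve$params[["E"]])
    sos <- min(max(sos, 1L), DAYS_PER_YEAR)
    eos <- min(max(eos, 1L), DAYS_PER_YEAR)
    return(list(sos = sos, eos = eos,
                sos_thresh = f[sos], eos_thresh = f[eos]))
  }
  sl <- diff(f)
  first <- seq_len(half_split - 1L)
  second <- half_split:(DAYS_PER_YEAR - 1L)
  # the date must be an interior extremum of the slope, not a year-boundary
  # artifact of the smooth reconstruction (polynomials especially swing at
  # the edges of the year)
  pick_extremum <- function(idx, s) {
    cand <- idx[idx > min(idx) & idx < max(idx)]
    cand <- cand[s[cand] > s[cand - 1L] & s[cand] >= s[cand + 1L]]
    if (length(cand) == 0) return(NA_integer_)
    m <- max(s[cand])
    cand[s[cand] >= m - 1e-9 * max(1, abs(m))][1]  # earliest tie wins
  }
  i_sos <- pick_extremum(first, sl)
  i_eos <- pick_extremum(second, -sl)
  sos <- if (!is.na(i_sos) && sl[i_sos] > 0) i_sos else NA_integer_
  eos <- if (!is.na(i_eos) && -sl[i_eos] > 0) i_eos else NA_integer_
  list(
    sos = sos, eos = eos,
    sos_thresh = if (is.na(sos)) NA_real_ else f[sos],
    eos_thresh = if (is.na(eos)) NA_real_ else f[eos]
  )
}

# Date one year's fitted daily curve against pixel thresholds.
annual_dates_from_fit <- function(f, sos_thresh, eos_thresh,
                                  half_split = 182L, windows = NULL) {
  if (any(!is.finite(f)) || !is.finite(sos_thresh) || !is.finite(eos_thresh)) {
    return(c(sos = NA_real_, eos = NA_real_))
  }
  if (is.null(windows)) {
    windows <- list(sos_window = c(1L, half_split),
                    eos_window = c(half_split + 1L, DAYS_PER_YEAR))
  }
  sos <- first_up_crossing(f, sos_thresh,
                           windows$sos_window[1], windows$sos_window[2])
  eos <- last_down_crossing(f, eos_thresh,
                            windows$eos_window[1], windows$eos_window[2])
  c(sos = sos, eos = eos)
}

#' Date an individual year against climatological thresholds
#'
#' The season start is the first upward crossing of the start threshold
#' within the start search window, the season end the last downward crossing
#' of the end threshold within the end window (both interpolated linearly
#' between daily grid points and rounded to the nearest integer day, half
#' up). Windows default to the half-year split and are adjusted by
#' [resolve_double_season()] when the year's curve is bimodal. A year whose
#' curve never crosses a threshold gets a missing date.
#'
#' @param curve the year's fitted `fp_curve` (same method as the
#'   climatological curve)
#' @param clim output of [climatological_dates()] for this pixel and method
#' @param half_split last day of the first half-year
#' @param check_double_season apply the double-season rules? Default `TRUE`.
#' @return list with integer `sos`, `eos` (or `NA`)
#' @export
annual_dates <- function(curve, clim, half_split = 182L,
                         check_double_season = TRUE) {
  d <- curve$diagnostics
  if (!isTRUE(d$converged) || isTRUE(d$non_seasonal)) {
    return(list(sos = NA_integer_, eos = NA_integer_))
  }
  windows <- if (check_double_season) {
    resolve_double_season(curve, clim$eos_thresh, clim$sos_thresh,
                          half_split = half_split)
  } else NULL
  xs <- annual_dates_from_fit(curve$fitted, clim$sos_thresh, clim$eos_thresh,
                              half_split, windows)
  list(sos = round_half_up(xs[["sos"]]), eos = round_half_up(xs[["eos"]]))
}

#' Combine per-method phenology into an ensemble
#'
#' The ensemble date is the arithmetic mean of the methods that produced a
#' date at a pixel-year, rounded to the nearest day (half up), and reported
#' only where at least `min_methods` methods are available.
#'
#' @param phen phenology tibble with a `method` column (per-method rows)
#' @param min_methods minimum number of contributing methods (default 2)
#' @return tibble of ensemble rows (`method = "ensemble"`)
#' @export
ensemble_phenology <- function(phen, min_methods = 2L) {
  phen |>
    dplyr::filter(.data$method != "ensemble") |>
    dplyr::group_by(.data$lat, .data$lon, .data$year) |>
    dplyr::summarise(
      n_sos = sum(!is.na(.data$sos)), n_eos = sum(!is.na(.data$eos)),
      sos = mean(.data$sos, na.rm = TRUE),
      eos = mean(.data$eos, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sos = ifelse(.data$n_sos >= min_methods,
                   as.numeric(round_half_up(.data$sos)), NA_real_),
      eos = ifelse(.data$n_eos >= min_methods,
                   as.numeric(round_half_up(.data$eos)), NA_real_),
      method = "ensemble",
      gsl = .data$eos - .data$sos
    ) |>
    dplyr::select("lat", "lon", "year", "method", "sos", "eos", "gsl")
}

#' Extract per-pixel, per-year phenology from an NDVI cube
#'
#' Runs the full dating scheme for each requested curve-fitting method and
#' adds the four-method ensemble: per pixel, the multi-year mean composites
#' are fitted and dated climatologically; each year's composites are then
#' fitted by the same method and dated by threshold crossing. Pixels whose
#' mean seasonal amplitude falls below `amplitude_floor` are flagged
#' non-seasonal and carry no dates.
#'
#' @param ndvi an `fp_ndvi_cube`
#' @param methods curve-fitting methods to run (see [fit_curve()])
#' @param amplitude_floor minimum climatological composite amplitude
#' @param min_methods minimum methods required for an ensemble date
#' @param half_split last day of the first half-year
#' @return tibble with columns lat, lon, year, method, sos, eos, gsl,
#'   including `method = "ensemble"` rows
#' @export
#' @examples
#' tr <- gen_truth(2, 2, seed = 1)
#' nd <- gen_ndvi(tr, 2000:2002, noise_sd = 0)
#' ph <- extract_phenology(nd, methods = "hants")
#' head(ph)
extract_phenology <- function(ndvi,
                              methods = c("hants", "polyfit",
                                          "double_logistic",
                                          "piecewise_logistic"),
                              amplitude_floor = 0.05, min_methods = 2L,
                              half_split = 182L) {
  stopifnot(inherits(ndvi, "fp_ndvi_cube"))
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("hants", "polyfit", "double_logistic",
                                   "piecewise_logistic"))
  n_lat <- length(ndvi$lat); n_lon <- length(ndvi$lon)
  n_px <- n_lat * n_lon; n_year <- length(ndvi$years)
  doys <- ndvi$composite_doy
  Y_all <- matrix(ndvi$values, nrow = 24L)    # cols: pixel fastest, then year
  clim <- matrix(rowMeans(array(ndvi$values, dim = c(24L * n_px, n_year))),
                 nrow = 24L)                  # 24 x n_px mean-year composites
  amp <- apply(clim, 2, function(col) diff(range(col)))
  seasonal <- is.finite(amp) & amp >= amplitude_floor
  px <- pixel_tibble(ndvi$lat, ndvi$lon)

  per_method <- lapply(methods, function(m) {
    sos_mat <- matrix(NA_real_, n_px, n_year)
    eos_mat <- matrix(NA_real_, n_px, n_year)
    if (m %in% c("hants", "polyfit")) {
      design <- if (m == "hants") harmonic_design else poly_design
      idx <- which(seasonal)
      if (length(idx) > 0) {
        clim_fit <- fit_linear_batch(doys, clim[, idx, drop = FALSE], design)
        # all annual curves for the seasonal pixels in one solve
        ann_cols <- as.vector(outer(idx, (seq_len(n_year) - 1L) * n_px, `+`))
        ann_fit <- fit_linear_batch(doys, Y_all[, ann_cols, drop = FALSE],
                                    design)
        for (k in seq_along(idx)) {
          cl_curve <- new_curve(clim_fit$daily[, k], m, converged = TRUE,
                                residual_sd = clim_fit$residual_sd[k])
          cd <- climatological_dates(cl_curve, half_split)
          if (is.na(cd$sos) && is.na(cd$eos)) next
          for (yi in seq_len(n_year)) {
            f <- ann_fit$daily[, (yi - 1L) * length(idx) + k]
            cv <- new_curve(f, m, converged = TRUE)
            ad <- annual_dates(cv, cd, half_split)
            sos_mat[idx[k], yi] <- ad$sos
            eos_mat[idx[k], yi] <- ad$eos
          }
        }
      }
    } else {
      for (p in which(seasonal)) {
        cl_curve <- fit_curve(clim[, p], doys, m,
                              amplitude_floor = amplitude_floor)
        if (!isTRUE(cl_curve$diagnostics$converged)) next
        cd <- climatological_dates(cl_curve, half_split)
        if (is.na(cd$sos) && is.na(cd$eos)) next
        ref_rmse <- cl_curve$diagnostics$residual_sd
        for (yi in seq_len(n_year)) {
          yv <- Y_all[, (yi - 1L) * n_px + p]
          cv <- fit_curve(yv, doys, m, amplitude_floor = amplitude_floor,
                          init = cl_curve$params, ref_rmse = ref_rmse)
          if (!isTRUE(cv$diagnostics$converged)) next
          ad <- annual_dates(cv, cd, half_split)
          sos_mat[p, yi] <- ad$sos
          eos_mat[p, yi] <- ad$eos
        }
      }
    }
    tibble::tibble(
      lat = rep(px$lat, times = n_year),
      lon = rep(px$lon, times = n_year),
      year = rep(ndvi$years, each = n_px),
      method = m,
      sos = as.vector(sos_mat),
      eos = as.vector(eos_mat)
    )
  })
  out <- dplyr::bind_rows(per_method)
  # invariant: a defined pair must satisfy sos < eos
  bad <- !is.na(out$sos) & !is.na(out$eos) & out$sos >= out$eos
  out$sos[bad] <- NA_real_
  out$eos[bad] <- NA_real_
  out$gsl <- out$eos - out$sos
  ens <- ensemble_phenology(out, min_methods = min_methods)
  dplyr::bind_rows(out, ens) |>
    dplyr::arrange(.data$method, dplyr::desc(.data$lat), .data$lon, .data$year)
}
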