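#' Filter a site phenology table for the decadal analysis
#'
#' Drops implausible site-years — leaf unfolding after the end of June
#' (DOY 181) or senescence before the beginning of July (DOY 182) — and
#' identifies the sites with a long enough record inside the study period:
#' at least `min_years` years of unfolding observations, of senescence
#' observations, and of both.
#'
#' @param records site table (site_id, lat, lon, year, unfold_doy,
#'   senesce_doy)
#' @param start_year,end_year study period (defaults 1982-2009)
#' @param min_years minimum observation years per site (default 28)
#' @param unfold_latest latest acceptable unfolding DOY (default 181)
#' @param senesce_earliest earliest acceptable senescence DOY (default 182)
#' @return list: `records` (filtered rows), `sites_unfolding`,
#'   `sites_senescence`, `sites_both` (character vectors of site ids)
#' @export
filter_sites <- function(records, start_year = 1982L, end_year = 2009L,
                         min_years = 28L, unfold_latest = 181L,
                         senesce_earliest = 182L) {
  rec <- records |>
    dplyr::filter(.data$year >= start_year, .data$year <= end_year) |>
    dplyr::mutate(
      unfold_doy = ifelse(!is.na(.data$unfold_doy) &
                            .data$unfold_doy > unfold_latest,
                          NA_integer_, .data$unfold_doy),
      senesce_doy = ifelse(!is.na(.data$senesce_doy) &
                             .data$senesce_doy < senesce_earliest,
                           NA_integer_, .data$senesce_doy)
    ) |>
    dplyr::filter(!is.na(.data$unfold_doy) | !is.na(.data$senesce_doy))
  tallies <- rec |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_unfold = sum(!is.na(.data$unfold_doy)),
      n_senesce = sum(!is.na(.data$senesce_doy)),
      n_both = sum(!is.na(.data$unfold_doy) & !is.na(.data$senesce_doy)),
      .groups = "drop"
    )
  list(
    records = rec,
    sites_unfolding = tallies$site_id[tallies$n_unfold >= min_years],
    sites_senescence = tallies$site_id[tallies$n_senesce >= min_years],
    sites_both = tallies$site_id[tallies$n_both >= min_years]
  )
}

#' Frost counts over site-observed growing seasons
#'
#' Counts frost days between each site's observed leaf unfolding and
#' senescence using the daily minima of the site's containing grid cell,
#' split at the summer solstice. Sites outside the grid are reported and
#' skipped. Site-years missing either date get missing counts.
#'
#' @param sites site table (site_id, lat, lon, year, unfold_doy,
#'   senesce_doy)
#' @param daily an `fp_daily_tmin`
#' @param cutoff_mode spring/autumn split rule
#' @return tibble: site_id, lat, lon, year, sos, eos, gsfd, spr_fd, fal_fd
#' @export
site_frost_counts <- function(sites, daily,
                              cutoff_mode = c("solstice", "midseason")) {
  cutoff_mode <- match.arg(cutoff_mode)
  ilat <- vapply(sites$lat, match_axis, integer(1), axis = daily$lat,
                 res = daily$resolution)
  ilon <- vapply(sites$lon, match_axis, integer(1), axis = daily$lon,
                 res = daily$resolution)
  outside <- is.na(ilat) | is.na(ilon)
  if (any(outside)) {
    warning(sum(outside), " site-year row(s) fall outside the grid; skipped",
            call. = FALSE)
  }
  s <- sites[!outside, ]
  win <- tibble::tibble(
    lat = daily$lat[ilat[!outside]], lon = daily$lon[ilon[!outside]],
    year = s$year,
    sos = as.numeric(s$unfold_doy), eos = as.numeric(s$senesce_doy)
  )
  # drop inverted site windows (unfolding after senescence is an outlier)
  bad <- !is.na(win$sos) & !is.na(win$eos) & win$sos >= win$eos
  win$sos[bad] <- NA_real_
  win$eos[bad] <- NA_real_
  counts <- frost_counts(daily, win, cutoff_mode)
  dplyr::bind_cols(tibble::tibble(site_id = s$site_id),
                   counts) |>
    dplyr::mutate(site_lat = s$lat, site_lon = s$lon)
}

#' Compare site-based and satellite-based decadal frost-day change
#'
#' Pairs each site with its containing grid cell, computes decadal mean
#' counts for both sources, and summarises the paired decadal deltas:
#' means, the paired difference, and the fraction of pairs whose deltas
#' agree in sign.
#'
#' @param site_counts output of [site_frost_counts()]
#' @param cell_counts satellite-based counts (tibble lat, lon, year, value
#'   column)
#' @param years_a,years_b year sets of the two decades
#' @param value count column to compare (default `"gsfd"`)
#' @param min_pairs minimum matched pairs (default 10)
#' @param min_years minimum valid years per decade per series (default 3)
#' @return list: `pairs` (per-site tibble with both deltas) and `summary`
#'   (one-row tibble)
#' @export
compare_decadal <- function(site_counts, cell_counts, years_a, years_b,
                            value = "gsfd", min_pairs = 10L, min_years = 3L) {
  delta_of <- function(df, keys) {
    df |>
      dplyr::filter(!is.na(.data[[value]]),
                    .data$year %in% c(years_a, years_b)) |>
      dplyr::mutate(.decade = ifelse(.data$year %in% years_a, "a", "b")) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$.decade) |>
      dplyr::summarise(m = mean(.data[[value]]), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::filter(.data$n >= min_years) |>
      tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                         names_from = ".decade", values_from = "m") |>
      dplyr::filter(!is.na(.data$a), !is.na(.data$b)) |>
      dplyr::mutate(delta = .data$b - .data$a)
  }
  site_d <- delta_of(site_counts, c("site_id", "lat", "lon"))
  cell_d <- delta_of(cell_counts, c("lat", "lon"))
  pairs <- dplyr::inner_join(
    dplyr::select(site_d, "site_id", "lat", "lon", site_delta = "delta"),
    dplyr::select(cell_d, "lat", "lon", cell_delta = "delta"),
    by = c("lat", "lon")
  )
  if (nrow(pairs) < min_pairs) {
    stop("fewer than ", min_pairs, " matched site-cell pairs", call. = FALSE)
  }
  tt <- stats::t.test(pairs$site_delta, mu = 0)
  summary <- tibble::tibble(
    n_pairs = nrow(pairs),
    site_mean_delta = mean(pairs$site_delta),
    site_sd_delta = sd(pairs$site_delta),
    site_p_value = tt$p.value,
    cell_mean_delta = mean(pairs$cell_delta),
    paired_diff = mean(pairs$site_delta - pairs$cell_delta),
    sign_agreement = mean(sign(pairs$site_delta) == sign(pairs$cell_delta))
  )
  list(pairs = pairs, summary = summary)
}
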