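#' Factorial fixed-driver frost-count scenario
#'
#' Separates the influence of phenology change from minimum-temperature
#' change by re-counting frost days with one driver held constant. Per draw,
#' one year is sampled uniformly from the record and used globally: in
#' `fix_phenology` mode that year's season windows are applied to every
#' year's temperatures (only temperature varies); in `fix_temperature` mode
#' that year's daily minima are applied under every year's phenology (only
#' phenology varies). Counts are averaged over `n_draws` draws to remove the
#' sampling bias of the drawn year.
#'
#' @param daily an `fp_daily_tmin`
#' @param phen phenology tibble for a single method (if a `method` column
#'   with several methods is present, the ensemble is used)
#' @param mode `"fix_phenology"` or `"fix_temperature"`
#' @param n_draws number of random draws (default 10)
#' @param seed master seed; draw years are a pure function of it
#' @param cutoff_mode spring/autumn split rule, see [frost_counts()]
#' @param keep_draws retain the per-draw count tables?
#' @return `fp_scenario`: draw years and seed, and `counts`, a tibble of
#'   per-pixel, per-year frost counts averaged over draws (columns gsfd,
#'   spr_fd, fal_fd)
#' @export
run_scenario <- function(daily, phen,
                         mode = c("fix_phenology", "fix_temperature"),
                         n_draws = 10L, seed = 0L,
                         cutoff_mode = c("solstice", "midseason"),
                         keep_draws = FALSE) {
  mode <- match.arg(mode)
  cutoff_mode <- match.arg(cutoff_mode)
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  if ("method" %in% names(phen) && length(unique(phen$method)) > 1) {
    if (!"ensemble" %in% phen$method) {
      stop("phenology table has several methods and no ensemble", call. = FALSE)
    }
    phen <- dplyr::filter(phen, .data$method == "ensemble")
  }
  years <- intersect(unique(phen$year), daily$years)
  if (length(years) == 0) {
    stop("phenology and temperature records share no years", call. = FALSE)
  }
  phen <- dplyr::filter(phen, .data$year %in% years)
  draw_years <- withr::with_seed(
    as.integer(seed), sample(years, n_draws, replace = TRUE)
  )
  acc <- NULL
  per_draw <- if (keep_draws) vector("list", n_draws) else NULL
  for (d in seq_len(n_draws)) {
    yd <- draw_years[d]
    if (mode == "fix_phenology") {
      fixed <- dplyr::filter(phen, .data$year == yd)
      phen_d <- purrr::map_dfr(years, function(y) {
        dplyr::mutate(fixed, year = y)
      })
      counts <- frost_counts(daily, phen_d, cutoff_mode)
    } else {
      iy <- match(yd, daily$years)
      daily_d <- daily
      daily_d$values <- daily$values[, rep(iy, length(daily$years)), , ,
                                     drop = FALSE]
      counts <- frost_counts(daily_d, phen, cutoff_mode)
    }
    if (keep_draws) per_draw[[d]] <- counts
    counts <- dplyr::select(counts, "lat", "lon", "year",
                            "gsfd", "spr_fd", "fal_fd")
    if (is.null(acc)) {
      acc <- counts
    } else {
      stopifnot(identical(acc$lat, counts$lat),
                identical(acc$year, counts$year))
      acc$gsfd <- acc$gsfd + counts$gsfd
      acc$spr_fd <- acc$spr_fd + counts$spr_fd
      acc$fal_fd <- acc$fal_fd + counts$fal_fd
    }
  }
  acc$gsfd <- acc$gsfd / n_draws
  acc$spr_fd <- acc$spr_fd / n_draws
  acc$fal_fd <- acc$fal_fd / n_draws
  structure(
    list(mode = mode, n_draws = as.integer(n_draws),
         seed = as.integer(seed), draw_years = draw_years,
         cutoff_mode = cutoff_mode, counts = acc, per_draw = per_draw),
    class = "fp_scenario"
  )
}

#' @export
print.fp_scenario <- function(x, ...) {
  cat("<fp_scenario> mode=", x$mode, ", ", x$n_draws,
      " draws (years ", paste(x$draw_years, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Label the dominant driver of frost-day change per pixel
#'
#' Compares the decadal change of the two fixed-driver scenarios: the pixel
#' is labeled by the scenario whose change is larger in absolute value
#' (`"temperature"` for the phenology-fixed run, `"phenology"` for the
#' temperature-fixed run), or `"mixed"` when the two magnitudes differ by
#' less than `tie_threshold` days.
#'
#' @param full change map of the unconstrained counts
#' @param scen_temp_only change map of the `fix_phenology` scenario (only
#'   temperature varies)
#' @param scen_phen_only change map of the `fix_temperature` scenario (only
#'   phenology varies)
#' @param tie_threshold magnitude difference below which the pixel is
#'   `"mixed"` (days; default 0.1)
#' @return tibble: lat, lon, delta_full, delta_temperature,
#'   delta_phenology, driver
#' @export
attribute_change <- function(full, scen_temp_only, scen_phen_only,
                             tie_threshold = 0.1) {
  sel <- function(x, nm) {
    x |> dplyr::select("lat", "lon", !!nm := "delta")
  }
  out <- sel(full, "delta_full") |>
    dplyr::inner_join(sel(scen_temp_only, "delta_temperature"),
                      by = c("lat", "lon")) |>
    dplyr::inner_join(sel(scen_phen_only, "delta_phenology"),
                      by = c("lat", "lon"))
  dt <- abs(out$delta_temperature); dp <- abs(out$delta_phenology)
  out$driver <- dplyr::case_when(
    is.na(dt) | is.na(dp) ~ NA_character_,
    abs(dt - dp) < tie_threshold ~ "mixed",
    dt > dp ~ "temperature",
    TRUE ~ "phenology"
  )
  out
}
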