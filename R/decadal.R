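#' Default decade definitions
#'
#' The satellite record starts in 1982, so the "1980s" is 1982-1989; the
#' 2000s runs to 2009 for comparisons against site records that end there,
#' or to 2012 for satellite-only analyses.
#'
#' @param satellite_2000s use 2000-2012 for the 2000s (default) rather than
#'   2000-2009
#' @return named list of year vectors
#' @export
decade_years <- function(satellite_2000s = TRUE) {
  list(
    `1980s` = 1982:1989,
    `1990s` = 1990:1999,
    `2000s` = if (satellite_2000s) 2000:2012 else 2000:2009
  )
}

#' Decadal mean of an annual per-pixel metric
#'
#' @param metric tibble with columns lat, lon, year and the value column
#' @param years the decade's years
#' @param value name of the value column (default `"gsfd"`)
#' @param min_years minimum valid years per pixel (default 7); pixels with
#'   fewer are missing
#' @return tibble lat, lon, mean, n_years
#' @export
decadal_mean <- function(metric, years, value = "gsfd", min_years = 7L) {
  metric |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::group_by(.data$lat, .data$lon) |>
    dplyr::summarise(
      n_years = sum(!is.na(.data[[value]])),
      mean = mean(.data[[value]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean = ifelse(.data$n_years >= min_years, .data$mean,
                                NA_real_))
}

# Welch two-sample t-test, vectorized over pixels. Returns delta = mean_b -
# mean_a and a two-sided p-value. Zero variance in both samples: equal means
# give p = 1 (no change), unequal means are significant by convention.
welch_test_vec <- function(mean_a, var_a, n_a, mean_b, var_b, n_b) {
  delta <- mean_b - mean_a
  se2 <- var_a / n_a + var_b / n_b
  p <- rep(NA_real_, length(delta))
  degenerate <- is.finite(se2) & se2 == 0
  ordinary <- is.finite(se2) & se2 > 0
  tstat <- delta[ordinary] / sqrt(se2[ordinary])
  df <- se2[ordinary]^2 /
    ((var_a / n_a)^2 / (n_a - 1) + (var_b / n_b)^2 / (n_b - 1))[ordinary]
  p[ordinary] <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- ifelse(delta[degenerate] == 0, 1, 0)
  list(delta = delta, p_value = p)
}

#' Between-decade change map with per-pixel significance
#'
#' Per pixel, a Welch (unequal-variance) two-sample t-test compares the
#' annual values of two decades; `delta` is the later minus the earlier
#' decade mean. Pixels where both decades have zero variance are declared
#' unchanged (p = 1) when the means agree and changed (p = 0) when they do
#' not.
#'
#' @param metric tibble with columns lat, lon, year and the value column
#' @param years_a,years_b year sets of the earlier and later decade
#' @param value name of the value column (default `"gsfd"`)
#' @param alpha significance level (default 0.05)
#' @param min_years minimum valid years per pixel in each decade (default 3)
#' @return `fp_change_map` tibble: lat, lon, delta, p_value, significant,
#'   n1, n2; attributes `alpha`, `value`
#' @export
difference_test <- function(metric, years_a, years_b, value = "gsfd",
                            alpha = 0.05, min_years = 3L) {
  stats_of <- function(years, suffix) {
    metric |>
      dplyr::filter(.data$year %in% years, !is.na(.data[[value]])) |>
      dplyr::group_by(.data$lat, .data$lon) |>
      dplyr::summarise(
        "mean_{suffix}" := mean(.data[[value]]),
        "var_{suffix}" := stats::var(.data[[value]]),
        "n_{suffix}" := dplyr::n(),
        .groups = "drop"
      )
  }
  ab <- dplyr::inner_join(stats_of(years_a, "a"), stats_of(years_b, "b"),
                          by = c("lat", "lon")) |>
    dplyr::filter(.data$n_a >= min_years, .data$n_b >= min_years)
  wt <- welch_test_vec(ab$mean_a, ab$var_a, ab$n_a,
                       ab$mean_b, ab$var_b, ab$n_b)
  out <- tibble::tibble(
    lat = ab$lat, lon = ab$lon,
    delta = wt$delta, p_value = wt$p_value,
    significant = !is.na(wt$p_value) & wt$p_value < alpha,
    n1 = ab$n_a, n2 = ab$n_b
  )
  attr(out, "alpha") <- alpha
  attr(out, "value") <- value
  class(out) <- c("fp_change_map", class(out))
  out
}

#' Area fraction of pixels changing in a given direction
#'
#' Fractions are area-weighted by the cosine of latitude over the valid
#' pixels of the map.
#'
#' @param change an `fp_change_map` (or any tibble with lat, delta,
#'   significant)
#' @param direction `"increase"` or `"decrease"`
#' @param require_significance count only significant pixels?
#' @return a single fraction in \[0, 1\]
#' @export
area_fraction <- function(change, direction = c("increase", "decrease"),
                          require_significance = TRUE) {
  direction <- match.arg(direction)
  valid <- !is.na(change$delta)
  if (!any(valid)) stop("change map has no valid pixels", call. = FALSE)
  w <- cos_lat_weights(change$lat, valid)
  hit <- if (direction == "increase") change$delta > 0 else change$delta < 0
  if (require_significance) hit <- hit & change$significant
  sum(w[valid & hit])
}

#' Area-weighted regional mean change with a one-sample test
#'
#' Restricts a change map to a region and reports the cos-latitude-weighted
#' mean and sd of the per-pixel deltas plus a one-sample t-test of the
#' deltas against zero.
#'
#' @param change an `fp_change_map`
#' @param mask logical vector along the rows of `change`, or a bounding box
#'   `c(lat_min, lat_max, lon_min, lon_max)`
#' @param min_pixels minimum valid pixels in the region (default 10)
#' @return one-row tibble: mean_delta, sd_delta, n, t, p_value
#' @export
region_mean_change <- function(change, mask = NULL, min_pixels = 10L) {
  keep <- if (is.null(mask)) rep(TRUE, nrow(change))
  else if (is.logical(mask)) mask
  else if (is.numeric(mask) && length(mask) == 4) {
    change$lat >= mask[1] & change$lat <= mask[2] &
      change$lon >= mask[3] & change$lon <= mask[4]
  } else stop("mask must be a logical vector or a bounding box", call. = FALSE)
  d <- change$delta[keep & !is.na(change$delta)]
  lat <- change$lat[keep & !is.na(change$delta)]
  if (length(d) < min_pixels) {
    stop("fewer than ", min_pixels, " valid pixels in the region",
         call. = FALSE)
  }
  w <- cos_lat_weights(lat)
  m <- sum(w * d)
  s <- sqrt(sum(w * (d - m)^2) * length(d) / max(length(d) - 1, 1))
  if (stats::sd(d) == 0) {
    # degenerate region: constant deltas, same convention as difference_test
    tstat <- if (m == 0) 0 else Inf * sign(m)
    pval <- if (m == 0) 1 else 0
  } else {
    tt <- stats::t.test(d, mu = 0)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  tibble::tibble(mean_delta = m, sd_delta = s, n = length(d),
                 t = tstat, p_value = pval)
}

#' Plot a change map
#' @param object an `fp_change_map`
#' @param ... unused
#' @return a ggplot: delta as filled tiles, significant pixels dotted
#' @export
autoplot.fp_change_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$delta)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        size = 0.3, shape = 20) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = paste0("Δ", attr(object, "value") %||% "value"),
                  title = "Decadal change (dots: P < alpha)") +
    ggplot2::theme_minimal()
}

#' Summarise a change map
#' @param x an `fp_change_map`
#' @param ... unused
#' @return one-row tibble with area fractions and mean delta
#' @export
glance.fp_change_map <- function(x, ...) {
  tibble::tibble(
    n_pixels = sum(!is.na(x$delta)),
    mean_delta = mean(x$delta, na.rm = TRUE),
    frac_sig_increase = area_fraction(x, "increase", TRUE),
    frac_sig_decrease = area_fraction(x, "decrease", TRUE),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' @export
tidy.fp_change_map <- function(x, ...) tibble::as_tibble(x)
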