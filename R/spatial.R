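#' First-order partial correlation
#'
#' Correlation between `x` and `y` after linearly removing a controlling
#' variable `z`: `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-sided p-value from the t transform on `n - 3` degrees of
#' freedom. Incomplete triples are dropped. Undefined when either variable
#' is perfectly collinear with the control.
#'
#' @param x,y,z numeric vectors of equal length
#' @param min_n minimum complete triples (default 4)
#' @return one-row tibble: r, p_value, n
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(100); x <- z + rnorm(100); y <- -z + rnorm(100)
#' partial_correlation(x, y, z)
partial_correlation <- function(x, y, z, min_n = 4L) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  miss <- tibble::tibble(r = NA_real_, p_value = NA_real_, n = n)
  if (n < min_n) return(miss)
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) return(miss)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= .Machine$double.eps) return(miss)
  r <- (rxy - rxz * ryz) / sqrt(den)
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 3) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 3)
  }
  tibble::tibble(r = r, p_value = p, n = n)
}

#' Moving-window partial correlations of frost-day change with its drivers
#'
#' For every grid cell, collects the valid pixels of the surrounding
#' `window_deg` x `window_deg` box (5 x 5 pixels on a half-degree grid;
#' windows are truncated at the grid edge) and computes two first-order
#' partial correlations over the window's pixels: frost-day change against
#' growing-season-length change controlling for temperature change
#' (`r_phen`), and against temperature change controlling for season length
#' (`r_temp`).
#'
#' @param deltas tibble with columns lat, lon, delta_gsfd, delta_gsl,
#'   delta_tmin (one row per pixel)
#' @param window_deg window size in degrees (default 2.5)
#' @param min_pixels minimum valid pixels per window (default 10)
#' @return `fp_partial_corr_map` tibble: lat, lon, r_phen, p_phen, r_temp,
#'   p_temp, n_eff
#' @export
moving_window_partial <- function(deltas, window_deg = 2.5, min_pixels = 10L) {
  lat_axis <- sort(unique(deltas$lat), decreasing = TRUE)
  lon_axis <- sort(unique(deltas$lon))
  res <- if (length(lon_axis) > 1) diff(lon_axis)[1] else
    if (length(lat_axis) > 1) abs(diff(lat_axis)[1]) else
      stop("grid has a single cell", call. = FALSE)
  half <- floor((window_deg / res) / 2)
  n_lat <- length(lat_axis); n_lon <- length(lon_axis)
  to_mat <- function(v) {
    m <- matrix(NA_real_, n_lat, n_lon)
    m[cbind(match(deltas$lat, lat_axis), match(deltas$lon, lon_axis))] <- v
    m
  }
  m_fd <- to_mat(deltas$delta_gsfd)
  m_gsl <- to_mat(deltas$delta_gsl)
  m_tmin <- to_mat(deltas$delta_tmin)
  out <- vector("list", n_lat * n_lon)
  k <- 0L
  for (j in seq_len(n_lon)) {
    jj <- max(1L, j - half):min(n_lon, j + half)
    for (i in seq_len(n_lat)) {
      ii <- max(1L, i - half):min(n_lat, i + half)
      x <- as.vector(m_gsl[ii, jj])
      y <- as.vector(m_fd[ii, jj])
      z <- as.vector(m_tmin[ii, jj])
      pc_phen <- partial_correlation(x, y, z, min_n = min_pixels)
      pc_temp <- partial_correlation(z, y, x, min_n = min_pixels)
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        lat = lat_axis[i], lon = lon_axis[j],
        r_phen = pc_phen$r, p_phen = pc_phen$p_value,
        r_temp = pc_temp$r, p_temp = pc_temp$p_value,
        n_eff = pc_phen$n
      )
    }
  }
  res_tbl <- dplyr::bind_rows(out)
  class(res_tbl) <- c("fp_partial_corr_map", class(res_tbl))
  attr(res_tbl, "window_deg") <- window_deg
  res_tbl
}

#' Plot a moving-window partial-correlation map
#' @param object an `fp_partial_corr_map`
#' @param which `"phen"` or `"temp"`
#' @param alpha dot significant cells at this level
#' @param ... unused
#' @export
autoplot.fp_partial_corr_map <- function(object, which = c("phen", "temp"),
                                         alpha = 0.05, ...) {
  which <- match.arg(which)
  rcol <- paste0("r_", which); pcol <- paste0("p_", which)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[rcol]])) +
    ggplot2::geom_point(
      data = dplyr::filter(df, !is.na(.data[[pcol]]), .data[[pcol]] < alpha),
      size = 0.3, shape = 20
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = rcol,
                  title = "Moving-window partial correlation") +
    ggplot2::theme_minimal()
}

#' Binned change density and quadrant percentages
#'
#' Two-dimensional histogram of per-pixel (phenology change, frost-day
#' change) pairs at integer-day bins, normalised to percent of valid pixels,
#' plus the percentage of pixels in each sign quadrant (positive vs
#' non-positive changes). Quadrant percentages sum to 100.
#'
#' @param delta_phen,delta_fd numeric vectors (days), one entry per pixel
#' @param bin bin width in days (default 1)
#' @return `fp_change_density`: list with `density` (tibble bin_phen,
#'   bin_fd, n, pct) and `quadrants` (tibble quadrant, n, pct)
#' @export
binned_change_density <- function(delta_phen, delta_fd, bin = 1) {
  ok <- complete.cases(delta_phen, delta_fd)
  dp <- delta_phen[ok]; df_ <- delta_fd[ok]
  n <- length(dp)
  if (n == 0) stop("no valid pixel pairs", call. = FALSE)
  dens <- tibble::tibble(
    bin_phen = floor(dp / bin) * bin,
    bin_fd = floor(df_ / bin) * bin
  ) |>
    dplyr::count(.data$bin_phen, .data$bin_fd, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / !!n)
  quad <- tibble::tibble(
    quadrant = dplyr::case_when(
      dp > 0 & df_ > 0 ~ "+phen/+fd",
      dp > 0 & df_ <= 0 ~ "+phen/-fd",
      dp <= 0 & df_ > 0 ~ "-phen/+fd",
      TRUE ~ "-phen/-fd"
    )
  ) |>
    dplyr::count(.data$quadrant, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / !!n)
  structure(list(density = dens, quadrants = quad, n = n, bin = bin),
            class = "fp_change_density")
}

#' @export
print.fp_change_density <- function(x, ...) {
  cat("<fp_change_density> ", x$n, " pixels, ", x$bin, "-day bins\n", sep = "")
  print(x$quadrants)
  invisible(x)
}

#' Plot a binned change density
#' @param object an `fp_change_density`
#' @param ... unused
#' @export
autoplot.fp_change_density <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(.data$bin_phen, .data$bin_fd,
                               fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Δ phenology (days)", y = "Δ frost days",
                  fill = "% of pixels") +
    ggplot2::theme_minimal()
}

#' Continental-scale association of frost-day change with season-length change
#'
#' Area-weighted (cos-latitude) least-squares slope of frost-day change on
#' growing-season-length change over all valid pixels, with a two-sided test
#' of the slope against zero.
#'
#' @param deltas tibble with columns lat, delta_gsl, delta_gsfd
#' @param min_pixels minimum valid pixels (default 30)
#' @return one-row tibble: slope, se, t, p_value, n
#' @export
continental_association <- function(deltas, min_pixels = 30L) {
  ok <- complete.cases(deltas$delta_gsl, deltas$delta_gsfd)
  d <- deltas[ok, ]
  if (nrow(d) < min_pixels) {
    stop("fewer than ", min_pixels, " valid pixels", call. = FALSE)
  }
  if (sd(d$delta_gsl) == 0) {
    return(tibble::tibble(slope = NA_real_, se = NA_real_, t = NA_real_,
                          p_value = NA_real_, n = nrow(d)))
  }
  fit <- stats::lm(delta_gsfd ~ delta_gsl, data = d,
                   weights = cos(d$lat * pi / 180))
  cf <- summary(fit)$coefficients
  tibble::tibble(slope = cf[2, 1], se = cf[2, 2], t = cf[2, 3],
                 p_value = cf[2, 4], n = nrow(d))
}

#' Assemble the per-pixel decadal change covariates for association analyses
#'
#' Joins the frost-day, season-length and temperature change maps into the
#' single pixel table consumed by [moving_window_partial()],
#' [binned_change_density()] and [continental_association()].
#'
#' @param change_gsfd,change_gsl,change_tmin `fp_change_map`s of GSFD, GSL
#'   and growing-season mean daily minimum temperature
#' @return tibble: lat, lon, delta_gsfd, delta_gsl, delta_tmin
#' @export
association_deltas <- function(change_gsfd, change_gsl, change_tmin) {
  sel <- function(x, nm) dplyr::select(tibble::as_tibble(x),
                                       "lat", "lon", !!nm := "delta")
  sel(change_gsfd, "delta_gsfd") |>
    dplyr::inner_join(sel(change_gsl, "delta_gsl"), by = c("lat", "lon")) |>
    dplyr::inner_join(sel(change_tmin, "delta_tmin"), by = c("lat", "lon"))
}

#' Growing-season mean daily minimum temperature per pixel-year
#'
#' The temperature covariate controlled for in the partial-correlation
#' analysis: the mean daily minimum over a fixed climatological window per
#' pixel (by default the pixel's ensemble-mean season), or over the whole
#' year.
#'
#' @param daily an `fp_daily_tmin`
#' @param phen phenology tibble; the climatological (multi-year mean) season
#'   of each pixel defines the window
#' @param window `"season"` (default) or `"annual"`
#' @return tibble: lat, lon, year, tmin_mean
#' @export
season_mean_tmin <- function(daily, phen = NULL,
                             window = c("season", "annual")) {
  window <- match.arg(window)
  px <- pixel_tibble(daily$lat, daily$lon)
  n_year <- length(daily$years)
  if (window == "annual" || is.null(phen)) {
    win <- dplyr::mutate(px, s = 1L, e = DAYS_PER_YEAR)
  } else {
    win <- phen |>
      dplyr::group_by(.data$lat, .data$lon) |>
      dplyr::summarise(s = round_half_up(mean(.data$sos, na.rm = TRUE)),
                       e = round_half_up(mean(.data$eos, na.rm = TRUE)),
                       .groups = "drop")
    win <- dplyr::left_join(px, win, by = c("lat", "lon"))
  }
  purrr::map_dfr(seq_len(n_year), function(yi) {
    means <- purrr::map_dbl(seq_len(nrow(win)), function(r) {
      if (is.na(win$s[r]) || is.na(win$e[r])) return(NA_real_)
      i <- match_axis(win$lat[r], daily$lat, daily$resolution)
      j <- match_axis(win$lon[r], daily$lon, daily$resolution)
      mean(daily$values[win$s[r]:win$e[r], yi, i, j])
    })
    tibble::tibble(lat = win$lat, lon = win$lon, year = daily$years[yi],
                   tmin_mean = means)
  })
}
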