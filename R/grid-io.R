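#' @name grid-io
#' @title Reading and writing gridded cubes and site tables
#' @description
#' Cubes travel as a self-describing plain-text format: `#key=value` header
#' lines (axes, units, calendar) followed by a CSV body with one column per
#' pixel (pixels ordered latitude-fastest, matching the in-memory arrays).
#' Values are written in shortest round-trip representation, so a write/read
#' cycle is bit-exact. Site phenology tables are ordinary CSV. All analysis
#' uses a fixed 365-day calendar: leap-day samples (Feb 29) present in real
#' data are dropped on read and later days renumbered.
NULL

fmt_axis <- function(x) paste(format(x, trim = TRUE, digits = 15), collapse = ",")
parse_axis <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

check_uniform_axis <- function(x, name, tol = 1e-6) {
  if (length(x) > 1) {
    steps <- diff(x)
    if (max(abs(steps - steps[1])) > tol) {
      stop("non-uniform ", name, " axis (spacing varies by more than ",
           tol, " degrees)", call. = FALSE)
    }
  }
  invisible(x)
}

cube_header <- function(cube) {
  if (inherits(cube, "fp_ndvi_cube")) {
    c("#frostphen-cube version=1", "#kind=ndvi", "#units=unitless",
      paste0("#lat=", fmt_axis(cube$lat)),
      paste0("#lon=", fmt_axis(cube$lon)),
      paste0("#years=", fmt_axis(cube$years)),
      paste0("#composite_doy=", fmt_axis(cube$composite_doy)))
  } else if (inherits(cube, "fp_tmin_cube")) {
    c("#frostphen-cube version=1", "#kind=tmin",
      paste0("#units=", cube$units),
      paste0("#lat=", fmt_axis(cube$lat)),
      paste0("#lon=", fmt_axis(cube$lon)),
      paste0("#years=", fmt_axis(cube$years)),
      paste0("#timestep_hours=", cube$timestep_hours),
      paste0("#hours=", fmt_axis(cube$hours)))
  } else {
    stop("not a cube", call. = FALSE)
  }
}

#' Write a cube to a plain-text file
#'
#' @param cube an `fp_ndvi_cube` or `fp_tmin_cube`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cube <- function(cube, path) {
  hdr <- cube_header(cube)
  n_lat <- length(cube$lat); n_lon <- length(cube$lon)
  n_px <- n_lat * n_lon
  px_names <- paste0("p", seq_len(n_px))
  if (inherits(cube, "fp_ndvi_cube")) {
    n_year <- length(cube$years)
    meta <- tibble::tibble(
      year = rep(cube$years, each = 24L),
      composite = rep(seq_len(24L), times = n_year),
      doy = rep(cube$composite_doy, times = n_year)
    )
    # rows ordered (composite fastest, then year); pixel columns lat-fastest
    arr <- aperm(cube$values, c(1, 4, 2, 3))
    body <- tibble::as_tibble(matrix(arr, nrow = 24L * n_year,
                                     dimnames = list(NULL, px_names)))
    body <- dplyr::bind_cols(meta, body)
  } else {
    spd <- dim(cube$values)[1]; n_year <- length(cube$years)
    meta <- tibble::tibble(
      year = rep(cube$years, each = spd * DAYS_PER_YEAR),
      doy = rep(rep(seq_len(DAYS_PER_YEAR), each = spd), times = n_year),
      hour = rep(cube$hours, times = DAYS_PER_YEAR * n_year)
    )
    body <- tibble::as_tibble(matrix(
      matrix(cube$values, nrow = spd * DAYS_PER_YEAR * n_year),
      nrow = spd * DAYS_PER_YEAR * n_year, dimnames = list(NULL, px_names)
    ))
    body <- dplyr::bind_cols(meta, body)
  }
  # %.17g guarantees bit-exact double round-trips through the text format
  body <- dplyr::mutate(body, dplyr::across(
    dplyr::all_of(px_names), ~ sprintf("%.17g", .x)
  ))
  writeLines(hdr, path)
  readr::write_csv(body, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

read_cube_header <- function(path) {
  lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0 || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  kv <- sub("^#", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(vals), keys)
}

#' Read a cube from a plain-text file
#'
#' Validates axes (uniform spacing, presence), checks units, auto-detects
#' Kelvin temperature input (values above 150) and converts to degrees C
#' with a warning, and enforces the fixed 365-day calendar: in years carrying
#' 366 days the Feb 29 samples (day 60) are dropped and subsequent days
#' renumbered, so every year has exactly 365 days after reading.
#'
#' @param path cube file written by [write_cube()] (or an equivalent dialect)
#' @return an `fp_ndvi_cube` or `fp_tmin_cube` according to the file header
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- read_cube_header(path)
  for (ax in c("lat", "lon")) {
    if (is.null(hdr[[ax]])) {
      stop("cube file is missing the ", ax, " axis", call. = FALSE)
    }
  }
  kind <- hdr$kind %||% stop("cube file is missing kind", call. = FALSE)
  lat <- check_uniform_axis(parse_axis(hdr$lat), "latitude")
  lon <- check_uniform_axis(parse_axis(hdr$lon), "longitude")
  years <- as.integer(parse_axis(hdr$years))
  # read everything as character and convert with base R's parser, which is
  # exactly round-trip for %.17g output
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  for (nm in intersect(c("year", "composite", "doy", "hour"), names(body))) {
    body[[nm]] <- as.integer(body[[nm]])
  }
  n_lat <- length(lat); n_lon <- length(lon); n_px <- n_lat * n_lon
  px_cols <- paste0("p", seq_len(n_px))
  if (!all(px_cols %in% names(body))) {
    stop("cube body does not match the declared grid (",
         n_px, " pixel columns expected)", call. = FALSE)
  }
  as_num_matrix <- function(df) {
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df))
  }
  if (kind == "ndvi") {
    vals <- as_num_matrix(body[px_cols])
    n_year <- length(years)
    if (nrow(vals) != 24L * n_year) {
      stop("NDVI cube must carry exactly 24 composites per year", call. = FALSE)
    }
    arr <- array(vals, dim = c(24L, n_year, n_lat, n_lon))
    arr <- aperm(arr, c(1, 3, 4, 2))
    structure(
      list(values = arr, years = years,
           composite_doy = as.integer(parse_axis(hdr$composite_doy)),
           lat = lat, lon = lon, resolution = axis_resolution(lat, lon),
           truth = NULL, noise_sd = NA_real_, seed = NA_integer_),
      class = "fp_ndvi_cube"
    )
  } else if (kind == "tmin") {
    units <- hdr$units %||% "degC"
    ts_h <- as.integer(hdr$timestep_hours)
    if (!ts_h %in% c(3L, 6L)) {
      stop("unsupported timestep_hours: ", ts_h, call. = FALSE)
    }
    spd <- 24L %/% ts_h
    body <- dplyr::arrange(body, .data$year, .data$doy, .data$hour)
    # 365-day calendar: drop Feb 29 and renumber in 366-day years
    by_year <- dplyr::count(body, .data$year, name = "n_samples")
    leap_years <- by_year$year[by_year$n_samples == 366L * spd]
    if (length(leap_years) > 0) {
      keep <- !(body$year %in% leap_years & body$doy == 60L)
      body <- body[keep, ]
      shift <- body$year %in% leap_years & body$doy > 60L
      body$doy[shift] <- body$doy[shift] - 1L
    }
    bad <- dplyr::count(body, .data$year, name = "n")
    if (any(bad$n != DAYS_PER_YEAR * spd)) {
      stop("temperature cube has incomplete days or years (expected ",
           DAYS_PER_YEAR * spd, " samples per year)", call. = FALSE)
    }
    vals <- as_num_matrix(body[px_cols])
    if (units %in% c("K", "kelvin") || stats::median(vals, na.rm = TRUE) > 150) {
      if (!units %in% c("K", "kelvin")) {
        warning("temperature values look like Kelvin (median > 150); ",
                "converting to degC", call. = FALSE)
      } else {
        warning("converting temperature from Kelvin to degC", call. = FALSE)
      }
      vals <- vals - 273.15
      units <- "degC"
    }
    arr <- array(vals, dim = c(spd, DAYS_PER_YEAR, length(years), n_lat, n_lon))
    structure(
      list(values = arr, timestep_hours = ts_h,
           hours = seq(0, 24 - ts_h, by = ts_h), years = years,
           lat = lat, lon = lon, resolution = axis_resolution(lat, lon),
           truth = NULL, units = units, seed = NA_integer_),
      class = "fp_tmin_cube"
    )
  } else {
    stop("unknown cube kind: ", kind, call. = FALSE)
  }
}

#' Aggregate a fine-resolution phenology grid onto a coarser grid
#'
#' Block-averages per-pixel dates onto a target resolution that is an integer
#' multiple of the fine resolution (e.g. 6 x 6 fine cells per coarse cell for
#' a 1/12 to 1/2 degree remap). A coarse cell is reported only where at least
#' `min_valid_frac` of its fine cells carry valid dates. The aggregator is
#' the arithmetic mean, which commutes with decadal differencing.
#'
#' @param phen phenology tibble (lat, lon, year, method, sos, eos, gsl)
#' @param target_resolution coarse cell size in degrees
#' @param min_valid_frac minimum fraction of valid fine cells per block
#' @return phenology tibble on the coarse grid
#' @export
remap_phenology <- function(phen, target_resolution, min_valid_frac = 0.5) {
  lat_axis <- sort(unique(phen$lat), decreasing = TRUE)
  lon_axis <- sort(unique(phen$lon))
  check_uniform_axis(rev(lat_axis), "latitude")
  check_uniform_axis(lon_axis, "longitude")
  fine_res <- if (length(lon_axis) > 1) diff(lon_axis)[1] else
    if (length(lat_axis) > 1) abs(diff(lat_axis)[1]) else target_resolution
  ratio <- target_resolution / fine_res
  if (abs(ratio - round(ratio)) > 1e-6) {
    stop("target resolution (", target_resolution,
         ") is not an integer multiple of the fine resolution (",
         fine_res, ")", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(phen)
  block_of <- function(axis_vals, axis) {
    idx <- match(axis_vals, axis)
    (idx - 1L) %/% ratio
  }
  phen |>
    dplyr::mutate(
      .blat = block_of(.data$lat, lat_axis),
      .blon = block_of(.data$lon, lon_axis)
    ) |>
    dplyr::group_by(.data$.blat, .data$.blon, .data$year, .data$method) |>
    dplyr::summarise(
      lat = mean(unique(.data$lat)),
      lon = mean(unique(.data$lon)),
      n_valid = sum(!is.na(.data$sos) & !is.na(.data$eos)),
      sos = mean(.data$sos, na.rm = TRUE),
      eos = mean(.data$eos, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ok = .data$n_valid >= min_valid_frac * ratio^2,
      sos = ifelse(.data$ok, .data$sos, NA_real_),
      eos = ifelse(.data$ok, .data$eos, NA_real_),
      gsl = .data$eos - .data$sos
    ) |>
    dplyr::select("lat", "lon", "year", "method", "sos", "eos", "gsl") |>
    dplyr::arrange(dplyr::desc(.data$lat), .data$lon, .data$year)
}

#' Read a site phenology table
#'
#' Expects columns `site_id, lat, lon, year, unfold_doy, senesce_doy`.
#' Day-of-year fields must be integers or empty; malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV file
#' @return typed tibble
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("site_id", "lat", "lon", "year", "unfold_doy", "senesce_doy")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("site table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_num <- function(x, col, integer = FALSE) {
    pat <- if (integer) "^-?[0-9]+$" else "^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"
    bad <- which(!is.na(x) & x != "" & !grepl(pat, x))
    if (length(bad) > 0) {
      stop("malformed ", col, " at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
    x[x == ""] <- NA
    if (integer) as.integer(x) else as.numeric(x)
  }
  tibble::tibble(
    site_id = raw$site_id,
    lat = check_num(raw$lat, "lat"),
    lon = check_num(raw$lon, "lon"),
    year = check_num(raw$year, "year", integer = TRUE),
    unfold_doy = check_num(raw$unfold_doy, "unfold_doy", integer = TRUE),
    senesce_doy = check_num(raw$senesce_doy, "senesce_doy", integer = TRUE)
  )
}

#' Write a site phenology table
#' @param sites tibble as produced by [gen_insitu()] or [read_site_table()]
#' @param path CSV file
#' @return `path`, invisibly
#' @export
write_site_table <- function(sites, path) {
  readr::write_csv(sites, path, progress = FALSE)
  invisible(path)
}
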