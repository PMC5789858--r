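#' Default configuration for a fully synthetic demonstration run
#'
#' @param out_dir output directory
#' @param seed master seed for the run
#' @return a config list understood by [run_pipeline()]
#' @export
demo_config <- function(out_dir = tempfile("frostphen_run_"), seed = 1L) {
  list(
    synthetic = list(n_lat = 16L, n_lon = 32L, n_sites = 40L),
    years = 1982:2012,
    timestep_hours = 3L,
    ndvi_noise_sd = 0.02,
    methods = c("hants", "polyfit", "double_logistic", "piecewise_logistic"),
    cutoff_mode = "solstice",
    n_draws = 10L,
    alpha = 0.05,
    satellite_2000s = TRUE,
    insitu_min_years = 28L,
    seed = as.integer(seed),
    out_dir = out_dir
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- demo_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]]) && !nm %in% c("synthetic")) {
      config[[nm]] <- defaults[[nm]]
    }
  }
  config$years <- as.integer(config$years)
  assert_years_contiguous(config$years)
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  if (is.null(config$synthetic)) {
    for (p in c("ndvi_path", "tmin_path")) {
      if (is.null(config[[p]])) {
        stop("config needs either `synthetic` parameters or `", p, "`",
             call. = FALSE)
      }
      if (!file.exists(config[[p]])) {
        stop("config path does not exist: ", config[[p]], call. = FALSE)
      }
    }
    if (!is.null(config$sites_path) && !file.exists(config$sites_path)) {
      stop("config path does not exist: ", config$sites_path, call. = FALSE)
    }
  }
  config
}

#' Run the full frost-exposure pipeline
#'
#' Orchestrates all stages from a config list or YAML file: data generation
#' (or ingestion), phenology extraction, frost counting, decadal change
#' mapping, factorial attribution, spatial association, and (when a site
#' table is available) the in-situ comparison. All tabular artifacts are
#' written as CSV in the output directory together with a `manifest.json`
#' recording the config, seeds and package version. A failing stage aborts
#' with the stage named and leaves a `FAILED` marker.
#'
#' @param config config list (see [demo_config()]) or path to a YAML file
#' @return invisibly, a named list of the in-memory results
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n", file = log_path,
        append = TRUE)
    message(paste("frostphen:", ...))
  }
  stage <- function(name, expr) {
    log_line("stage", name, "...")
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list(config = config)
  years <- config$years

  # --- data ------------------------------------------------------------
  dat <- stage("data", {
    if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      ranges <- do.call(truth_ranges, sy$ranges %||% list())
      truth <- gen_truth(sy$n_lat, sy$n_lon, ranges, seed = config$seed)
      ndvi <- gen_ndvi(truth, years, noise_sd = config$ndvi_noise_sd,
                       seed = config$seed + 1L)
      tmin <- gen_tmin(truth, years, timestep_hours = config$timestep_hours,
                       seed = config$seed + 2L)
      sites <- if (!is.null(sy$n_sites) && sy$n_sites > 0) {
        gen_insitu(truth, sy$n_sites, years, seed = config$seed + 3L)
      }
      list(truth = truth, ndvi = ndvi, tmin = tmin, sites = sites)
    } else {
      list(
        truth = NULL,
        ndvi = read_cube(config$ndvi_path),
        tmin = read_cube(config$tmin_path),
        sites = if (!is.null(config$sites_path))
          read_site_table(config$sites_path)
      )
    }
  })
  results$truth <- dat$truth

  # --- phenology -------------------------------------------------------
  phen <- stage("phenology", extract_phenology(dat$ndvi,
                                               methods = config$methods))
  readr::write_csv(phen, file.path(out_dir, "phenology.csv"), progress = FALSE)
  results$phenology <- phen
  phen_ens <- dplyr::filter(phen, .data$method == "ensemble")

  # --- frost counting --------------------------------------------------
  daily <- stage("frost", daily_min(dat$tmin))
  counts <- stage("frost", frost_counts(daily, phen_ens,
                                        cutoff_mode = config$cutoff_mode))
  readr::write_csv(counts, file.path(out_dir, "frost_counts.csv"),
                   progress = FALSE)
  results$counts <- counts

  # --- decadal change --------------------------------------------------
  decades <- decade_years(config$satellite_2000s)
  decades <- lapply(decades, function(d) intersect(d, years))
  pairs <- list(c("1980s", "2000s"), c("1980s", "1990s"), c("1990s", "2000s"))
  changes <- stage("change", {
    out <- list()
    for (pr in pairs) {
      for (v in c("gsfd", "spr_fd", "fal_fd")) {
        cm <- difference_test(counts, decades[[pr[1]]], decades[[pr[2]]],
                              value = v, alpha = config$alpha)
        key <- paste(v, pr[1], pr[2], sep = "_")
        readr::write_csv(cm, file.path(out_dir, paste0("change_", key, ".csv")),
                         progress = FALSE)
        out[[key]] <- cm
      }
    }
    out
  })
  results$changes <- changes

  # --- attribution -----------------------------------------------------
  attribution <- stage("attribute", {
    sc_t <- run_scenario(daily, phen_ens, "fix_phenology",
                         n_draws = config$n_draws, seed = config$seed + 10L,
                         cutoff_mode = config$cutoff_mode)
    sc_p <- run_scenario(daily, phen_ens, "fix_temperature",
                         n_draws = config$n_draws, seed = config$seed + 11L,
                         cutoff_mode = config$cutoff_mode)
    ya <- decades[["1980s"]]; yb <- decades[["2000s"]]
    ch_t <- difference_test(sc_t$counts, ya, yb, alpha = config$alpha)
    ch_p <- difference_test(sc_p$counts, ya, yb, alpha = config$alpha)
    dom <- attribute_change(changes[["gsfd_1980s_2000s"]], ch_t, ch_p)
    readr::write_csv(dom, file.path(out_dir, "attribution.csv"),
                     progress = FALSE)
    list(scenario_temperature = sc_t, scenario_phenology = sc_p,
         change_temperature = ch_t, change_phenology = ch_p, dominance = dom)
  })
  results$attribution <- attribution

  # --- spatial association ---------------------------------------------
  association <- stage("associate", {
    ya <- decades[["1980s"]]; yb <- decades[["2000s"]]
    ch_gsl <- difference_test(phen_ens, ya, yb, value = "gsl",
                              alpha = config$alpha)
    tmin_season <- season_mean_tmin(daily, phen_ens)
    ch_tmin <- difference_test(tmin_season, ya, yb, value = "tmin_mean",
                               alpha = config$alpha)
    deltas <- association_deltas(changes[["gsfd_1980s_2000s"]], ch_gsl,
                                 ch_tmin)
    pcm <- moving_window_partial(deltas)
    dens <- binned_change_density(deltas$delta_gsl, deltas$delta_gsfd)
    cont <- continental_association(deltas)
    readr::write_csv(pcm, file.path(out_dir, "partial_correlations.csv"),
                     progress = FALSE)
    readr::write_csv(dens$density, file.path(out_dir, "change_density.csv"),
                     progress = FALSE)
    readr::write_csv(dens$quadrants,
                     file.path(out_dir, "change_quadrants.csv"),
                     progress = FALSE)
    readr::write_csv(cont, file.path(out_dir, "continental_association.csv"),
                     progress = FALSE)
    list(deltas = deltas, partial = pcm, density = dens, continental = cont)
  })
  results$association <- association

  # --- in-situ comparison ----------------------------------------------
  if (!is.null(dat$sites)) {
    results$insitu <- stage("insitu", {
      flt <- filter_sites(dat$sites,
                          start_year = min(years),
                          end_year = min(max(years), 2009L),
                          min_years = config$insitu_min_years)
      keep <- flt$records$site_id %in% flt$sites_both
      sc <- site_frost_counts(flt$records[keep, ], daily,
                              cutoff_mode = config$cutoff_mode)
      cmp <- compare_decadal(sc, counts,
                             decades[["1980s"]],
                             intersect(decades[["1990s"]], years))
      readr::write_csv(cmp$summary, file.path(out_dir, "insitu_summary.csv"),
                       progress = FALSE)
      list(filtered = flt, site_counts = sc, comparison = cmp)
    })
  }

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    package = "frostphen",
    version = as.character(utils::packageVersion("frostphen")),
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    scenario_draw_years = list(
      fix_phenology = attribution$scenario_temperature$draw_years,
      fix_temperature = attribution$scenario_phenology$draw_years
    ),
    n_pixels = length(dat$ndvi$lat) * length(dat$ndvi$lon),
    years = range(years)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("done")
  invisible(results)
}
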