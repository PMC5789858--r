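# Shared synthetic fixtures, generated in code and cached for the session.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, force(expr), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# degenerate ranges pinning every truth field to a constant
constant_ranges <- function(sos0 = 120, eos0 = 280, sos_trend = 0,
                            eos_trend = 0, ndvi_winter = 0.1,
                            ndvi_amplitude = 0.6, tmin_annual_mean = 5,
                            tmin_seasonal_amplitude = 0,
                            tmin_diurnal_amplitude = 0, tmin_trend = 0,
                            tmin_ar1 = 0, tmin_noise_sd = 0) {
  truth_ranges(
    sos0 = c(sos0, sos0), eos0 = c(eos0, eos0),
    sos_trend = c(sos_trend, sos_trend), eos_trend = c(eos_trend, eos_trend),
    ndvi_winter = c(ndvi_winter, ndvi_winter),
    ndvi_amplitude = c(ndvi_amplitude, ndvi_amplitude),
    tmin_annual_mean = c(tmin_annual_mean, tmin_annual_mean),
    tmin_seasonal_amplitude = c(tmin_seasonal_amplitude,
                                tmin_seasonal_amplitude),
    tmin_diurnal_amplitude = c(tmin_diurnal_amplitude,
                               tmin_diurnal_amplitude),
    tmin_trend = c(tmin_trend, tmin_trend),
    tmin_ar1 = c(tmin_ar1, tmin_ar1),
    tmin_noise_sd = c(tmin_noise_sd, tmin_noise_sd)
  )
}

# a small weather world shared by frost/attribution tests
small_world <- function() {
  cached("small_world", {
    tr <- gen_truth(3, 4, seed = 11)
    tm <- gen_tmin(tr, 2000:2009, timestep_hours = 6, seed = 12)
    list(truth = tr, tmin = tm, daily = daily_min(tm),
         phen = truth_phenology_grid(tr, 2000:2009))
  })
}

# build a single-pixel daily-minimum object from a vector of daily values
daily_from_vector <- function(v, years = 2000L, lat = 50.25, lon = 10.25) {
  n_year <- length(years)
  stopifnot(length(v) == 365 * n_year)
  structure(
    list(values = array(v, dim = c(365L, n_year, 1L, 1L)),
         years = years, lat = lat, lon = lon, units = "degC",
         resolution = 0.5),
    class = "fp_daily_tmin"
  )
}

# evaluate the composite sampling of a double-logistic season
dl_composites <- function(winter = 0.1, amplitude = 0.6, sos = 120,
                          eos = 280, k = 0.15,
                          doys = frostphen:::composite_midpoints()) {
  double_logistic(doys, winter, amplitude, sos, eos, k, k)
}
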