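test_that("gen_truth honors degenerate ranges, seeds, and rejects bad ranges", {
  rng <- constant_ranges(sos0 = 120, eos0 = 280, tmin_annual_mean = 5,
                         tmin_ar1 = 0.5, tmin_noise_sd = 2)
  tr <- gen_truth(1, 1, rng, seed = 0)
  expect_equal(tr$sos0[1, 1], 120)
  expect_equal(tr$eos0[1, 1], 280)
  expect_equal(tr$tmin_annual_mean[1, 1], 5)
  expect_equal(tr$tmin_ar1[1, 1], 0.5)

  a <- gen_truth(10, 20, seed = 1)
  b <- gen_truth(10, 20, seed = 1)
  expect_identical(a, b)
  c <- gen_truth(10, 20, seed = 2)
  expect_false(identical(a$sos0, c$sos0))

  # ranges allowing eos0 <= sos0 + 30 are rejected
  expect_error(
    gen_truth(2, 2, truth_ranges(sos0 = c(110, 145), eos0 = c(130, 300))),
    "30 days"
  )
  expect_error(
    gen_truth(2, 2, truth_ranges(tmin_ar1 = c(0.5, 1.0))),
    "\\[0, 1\\)"
  )
  # every pixel satisfies the invariants under the defaults
  big <- gen_truth(8, 8, seed = 3)
  expect_true(all(big$eos0 - big$sos0 >= 30))
  expect_true(all(big$ndvi_winter + big$ndvi_amplitude <= 1))
  expect_true(all(big$tmin_ar1 >= 0 & big$tmin_ar1 < 1))
})

test_that("noiseless NDVI follows the double-logistic truth exactly", {
  rng <- constant_ranges(sos0 = 120, eos0 = 280)
  tr <- gen_truth(1, 1, rng, seed = 0)
  nd <- gen_ndvi(tr, 2000:2002, noise_sd = 0)
  # inflection point = winter + half amplitude (up to the far tail of the
  # falling logistic, ~4e-11 here)
  expect_equal(double_logistic(120, 0.1, 0.6, 120, 280),
               0.1 + 0.3, tolerance = 1e-9)
  # each composite equals the analytic curve at its mid-day
  expect_equal(nd$values[, 1, 1, 1],
               double_logistic(nd$composite_doy, 0.1, 0.6, 120, 280),
               tolerance = 1e-12)
  # without trends, all years are identical
  expect_equal(nd$values[, 1, 1, 1], nd$values[, 1, 1, 3])
  # 24 strictly increasing mid-composite days
  expect_length(nd$composite_doy, 24)
  expect_true(all(diff(nd$composite_doy) > 0))
  expect_error(gen_ndvi(tr, c(2000, 2002)), "contiguous")
})

test_that("NDVI composite noise has the requested spread", {
  tr <- gen_truth(4, 5, seed = 2)
  clean <- gen_ndvi(tr, 2001:2003, noise_sd = 0)
  noisy <- gen_ndvi(tr, 2001:2003, noise_sd = 0.02, seed = 9)
  res <- as.vector(noisy$values - clean$values)
  expect_gt(length(res), 1000)
  expect_lt(abs(sd(res) - 0.02) / 0.02, 0.2)
  # determinism
  again <- gen_ndvi(tr, 2001:2003, noise_sd = 0.02, seed = 9)
  expect_identical(noisy$values, again$values)
})

test_that("gen_tmin reproduces constant fields, linear trends and AR(1) noise", {
  rng0 <- constant_ranges(tmin_annual_mean = 5)
  tr0 <- gen_truth(1, 1, rng0, seed = 0)
  tm <- gen_tmin(tr0, 2000:2001, timestep_hours = 6, seed = 1)
  expect_true(all(tm$values == 5))

  rng_tr <- constant_ranges(tmin_annual_mean = 5, tmin_trend = 0.1)
  tr1 <- gen_truth(1, 1, rng_tr, seed = 0)
  tm1 <- gen_tmin(tr1, 2000:2010, timestep_hours = 6, seed = 1)
  annual <- apply(tm1$values[, , , 1, 1], 3, mean)
  expect_equal(annual[11] - annual[1], 1.0, tolerance = 1e-12)

  rng_ar <- constant_ranges(tmin_annual_mean = 0, tmin_ar1 = 0.7,
                            tmin_noise_sd = 3)
  tr2 <- gen_truth(1, 1, rng_ar, seed = 0)
  tm2 <- gen_tmin(tr2, 1981:2010, timestep_hours = 6, seed = 4)
  d <- daily_min(tm2)$values[, , 1, 1]
  ac <- stats::acf(as.vector(d), lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac - 0.7), 0.1)

  expect_error(gen_tmin(tr2, 2000, timestep_hours = 4), "3 or 6")
})

test_that("diurnal cycle puts the coldest sample at 06:00", {
  rng <- constant_ranges(tmin_annual_mean = 5, tmin_diurnal_amplitude = 3)
  tr <- gen_truth(1, 1, rng, seed = 0)
  tm <- gen_tmin(tr, 2000, timestep_hours = 3, seed = 0)
  day1 <- tm$values[, 1, 1, 1, 1]
  expect_equal(tm$hours[which.min(day1)], 6)
  expect_equal(min(day1), 5 - 3, tolerance = 1e-12)
})

test_that("gen_insitu reports truth exactly when noiseless and drops years binomially", {
  tr <- gen_truth(3, 4, constant_ranges(sos0 = 130, eos0 = 270,
                                        sos_trend = -0.5), seed = 0)
  tab <- gen_insitu(tr, 5, 2000:2004, obs_noise_sd = 0, missing_rate = 0,
                    seed = 1)
  expect_equal(nrow(tab), 25)
  expect_equal(tab$unfold_doy,
               frostphen:::round_half_up(130 - 0.5 * (tab$year - 2000)))
  expect_true(all(tab$senesce_doy == 270))

  tab2 <- gen_insitu(tr, 100, 1982:2009, missing_rate = 0.5, seed = 2)
  n <- nrow(tab2)
  # binomial 99% interval around 1400 of 2800
  expect_true(n >= 1400 - 2.576 * sqrt(2800 * 0.25) &
                n <= 1400 + 2.576 * sqrt(2800 * 0.25))
  expect_identical(tab2, gen_insitu(tr, 100, 1982:2009, missing_rate = 0.5,
                                    seed = 2))
  expect_error(gen_insitu(tr, 0, 2000), ">= 1")
  expect_error(gen_insitu(tr, 5, 2000, missing_rate = 1), "\\[0, 1\\)")
})
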