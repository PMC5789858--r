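doys <- frostphen:::composite_midpoints()

test_that("logistic fits recover noiseless transition days within a day", {
  y <- dl_composites(sos = 120, eos = 280)
  for (m in c("double_logistic", "piecewise_logistic")) {
    cf <- fit_curve(y, doys, m)
    expect_true(cf$diagnostics$converged)
    expect_lt(abs(cf$params[["S"]] - 120), 1)
    expect_lt(abs(cf$params[["E"]] - 280), 1)
  }
})

test_that("constant or weak-amplitude input is flagged non-seasonal with no dates", {
  cf <- fit_curve(rep(0.3, 24), doys, "double_logistic")
  expect_true(cf$diagnostics$non_seasonal)
  cd <- climatological_dates(cf)
  expect_true(is.na(cd$sos) && is.na(cd$eos))
  # below the default 0.05 amplitude floor
  cf2 <- fit_curve(0.3 + 0.02 * sin(2 * pi * doys / 365), doys, "hants")
  expect_true(cf2$diagnostics$non_seasonal)
})

test_that("harmonic fit peaks near the true seasonal midpoint", {
  y <- dl_composites(sos = 140, eos = 240)   # symmetric about DOY 190
  cf <- fit_curve(y, doys, "hants")
  expect_lt(abs(which.max(cf$fitted) - 190), 2.5)
})

test_that("climatological dates sit at the inflection with half-amplitude thresholds", {
  y <- dl_composites(winter = 0.1, amplitude = 0.6, sos = 120, eos = 280)
  cf <- fit_curve(y, doys, "double_logistic")
  cd <- climatological_dates(cf)
  expect_lt(abs(cd$sos - 120), 2.5)
  expect_lt(abs(cd$eos - 280), 2.5)
  expect_lt(abs(cd$sos_thresh - 0.4), 0.02)
  expect_lt(abs(cd$eos_thresh - 0.4), 0.02)
  # slope-scan methods land close as well
  cfh <- fit_curve(y, doys, "hants")
  cdh <- climatological_dates(cfh)
  expect_lt(abs(cdh$sos - 120), 10)
  expect_lt(abs(cdh$eos - 280), 10)
})

test_that("a time-mirrored curve swaps the roles of the two dates", {
  f <- double_logistic(1:365, 0.1, 0.6, 120, 260)
  cv <- frostphen:::new_curve(f, "hants", converged = TRUE)
  cd <- climatological_dates(cv)
  cv_rev <- frostphen:::new_curve(rev(f), "hants", converged = TRUE)
  cd_rev <- climatological_dates(cv_rev)
  expect_lt(abs(cd_rev$sos - (366 - cd$eos)), 1.5)
  expect_lt(abs(cd_rev$eos - (366 - cd$sos)), 1.5)
})

test_that("tied slope maxima resolve to the earliest day", {
  sl <- rep(0.001, 364)
  sl[c(50, 90)] <- 0.01                 # two identical interior slope peaks
  sl[250] <- -0.2                       # a clear fall for the second half
  f <- 0.1 + cumsum(c(0, sl))
  cv <- frostphen:::new_curve(f, "hants", converged = TRUE)
  cd <- climatological_dates(cv)
  expect_equal(cd$sos, 50L)
})

test_that("annual threshold dating is self-consistent and shift-equivariant", {
  y <- dl_composites(sos = 120, eos = 280)
  for (m in c("hants", "polyfit", "double_logistic", "piecewise_logistic")) {
    cf <- fit_curve(y, doys, m)
    cd <- climatological_dates(cf)
    ad <- annual_dates(cf, cd)
    expect_lte(abs(ad$sos - cd$sos), 1)
    expect_lte(abs(ad$eos - cd$eos), 1)
    # the same season 10 days later
    y10 <- dl_composites(sos = 130, eos = 290)
    cf10 <- fit_curve(y10, doys, m)
    ad10 <- annual_dates(cf10, cd)
    expect_lte(abs(ad10$sos - (ad$sos + 10)), 2)
    expect_lte(abs(ad10$eos - (ad$eos + 10)), 2)
  }
})

test_that("a year that never reaches the threshold gets missing dates", {
  y <- dl_composites(winter = 0.1, amplitude = 0.6, sos = 120, eos = 280)
  cf <- fit_curve(y, doys, "double_logistic")
  cd <- climatological_dates(cf)
  y_weak <- dl_composites(winter = 0.1, amplitude = 0.15, sos = 120,
                          eos = 280)
  cf_weak <- fit_curve(y_weak, doys, "double_logistic")
  ad <- annual_dates(cf_weak, cd)
  expect_true(is.na(ad$sos))
  expect_true(is.na(ad$eos))
})

test_that("double growing seasons follow the first-start/second-end rules", {
  two_season <- function(eos2) {
    double_logistic(1:365, 0.1, 0.5, 60, 140) +
      double_logistic(1:365, 0, 0.5, 200, eos2)
  }
  # both seasons complete: SOS from season 1, EOS from season 2
  f <- two_season(300)
  cv <- frostphen:::new_curve(f, "hants", converged = TRUE)
  rule <- resolve_double_season(cv, eos_thresh = 0.35, sos_thresh = 0.35)
  expect_true(rule$bimodal)
  ad <- frostphen:::annual_dates_from_fit(f, 0.35, 0.35, windows = rule)
  expect_lt(abs(ad[["sos"]] - 60), 3)
  expect_lt(abs(ad[["eos"]] - 300), 3)
  # second season ends next year: both dates from season 1
  f2 <- two_season(450)
  cv2 <- frostphen:::new_curve(f2, "hants", converged = TRUE)
  rule2 <- resolve_double_season(cv2, eos_thresh = 0.35, sos_thresh = 0.35)
  expect_true(rule2$bimodal)
  ad2 <- frostphen:::annual_dates_from_fit(f2, 0.35, 0.35, windows = rule2)
  expect_lt(abs(ad2[["sos"]] - 60), 3)
  expect_lt(abs(ad2[["eos"]] - 140), 3)
  # unimodal curves keep the identity rule
  f1 <- double_logistic(1:365, 0.1, 0.6, 120, 280)
  cv1 <- frostphen:::new_curve(f1, "hants", converged = TRUE)
  expect_false(resolve_double_season(cv1, 0.4, 0.4)$bimodal)
})

test_that("the ensemble averages available methods with a coverage minimum", {
  base <- tibble::tibble(lat = 50, lon = 10, year = 2000,
                         method = c("hants", "polyfit", "double_logistic",
                                    "piecewise_logistic"),
                         sos = c(118, 120, 122, 124),
                         eos = c(280, 280, 280, 280), gsl = eos - sos)
  ens <- ensemble_phenology(base)
  expect_equal(ens$sos, 121)
  expect_equal(ens$eos, 280)
  base$sos <- c(120, 120, 120, 120)
  expect_equal(ensemble_phenology(base)$sos, 120)
  base$sos <- c(119, NA, NA, NA)
  expect_true(is.na(ensemble_phenology(base, min_methods = 2)$sos))
})

test_that("extraction recovers truth on a small noiseless world", {
  tr <- gen_truth(3, 4, seed = 21)
  yrs <- 2000:2004
  nd <- gen_ndvi(tr, yrs, noise_sd = 0)
  ph <- extract_phenology(nd)
  truth <- truth_phenology_grid(tr, yrs)
  cmp <- dplyr::inner_join(dplyr::filter(ph, method == "ensemble"), truth,
                           by = c("lat", "lon", "year"),
                           suffix = c("", "_true"))
  expect_lt(mean(abs(cmp$sos - cmp$sos_true), na.rm = TRUE), 3)
  expect_lt(mean(abs(cmp$eos - cmp$eos_true), na.rm = TRUE), 3)
  # invariant: wherever both dates exist, sos < eos and gsl matches
  both <- dplyr::filter(ph, !is.na(sos), !is.na(eos))
  expect_true(all(both$sos < both$eos))
  expect_equal(both$gsl, both$eos - both$sos)
})
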