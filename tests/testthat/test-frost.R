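test_that("daily_min reduces sub-daily samples to per-day minima", {
  rng <- constant_ranges(tmin_annual_mean = 5)
  tr <- gen_truth(1, 1, rng, seed = 1)
  tm <- gen_tmin(tr, 2000, timestep_hours = 3, seed = 1)
  expect_true(all(daily_min(tm)$values == 5))

  tm$values[, 40, 1, 1, 1] <- c(2, 1, -3, 0, 4, 6, 5, 3)
  expect_equal(daily_min(tm)$values[40, 1, 1, 1], -3)

  # brute-force oracle on a structured cube
  w <- small_world()
  dl <- w$daily
  for (px in list(c(1, 1), c(3, 4))) {
    for (yi in c(1, 7)) {
      brute <- apply(w$tmin$values[, , yi, px[1], px[2]], 2, min)
      expect_equal(dl$values[, yi, px[1], px[2]], brute)
    }
  }
  tm$values[3, 100, 1, 1, 1] <- NA
  expect_error(daily_min(tm), "complete days")
})

test_that("count_frost_days counts strict sub-zero days in a closed window", {
  v <- rep(5, 365)
  expect_equal(count_frost_days(v, 1, 365), 0)
  v[150:159] <- -1
  expect_equal(count_frost_days(v, 145, 200), 10)
  expect_equal(count_frost_days(v, 150, 159), 10)
  expect_equal(count_frost_days(v, 151, 159), 9)
  expect_true(is.na(count_frost_days(v, NA, 200)))
  expect_error(count_frost_days(v, 200, 100), "start_doy")
  # a day at exactly 0.0 degC is not a frost day
  v0 <- rep(5, 365); v0[100] <- 0; v0[101] <- -1e-9
  expect_equal(count_frost_days(v0, 1, 365), 1)
})

test_that("spring/autumn split follows the cutoff conventions", {
  v <- rep(5, 365)
  v[c(155, 160, 200)] <- -2
  expect_equal(split_counts(v, 150, 250, "solstice"),
               c(spr_fd = 2L, fal_fd = 1L))
  # season ending before the solstice is all spring
  expect_equal(split_counts(v, 150, 170, "solstice"),
               c(spr_fd = 2L, fal_fd = 0L))
  # season starting after the solstice is all autumn
  expect_equal(split_counts(v, 180, 250, "solstice"),
               c(spr_fd = 0L, fal_fd = 1L))
  # midseason cutoff: sos=100, eos=301 -> cutoff 200 (day 200 in spring)
  expect_equal(split_counts(v, 100, 301, "midseason"),
               c(spr_fd = 3L, fal_fd = 0L))
  expect_equal(sum(split_counts(v, 100, 301, "midseason")),
               sum(split_counts(v, 100, 301, "solstice")))
})

test_that("timing histograms bin offsets from the season edges and sum to the split", {
  v <- rep(5, 365)
  sos <- 140; eos <- 260
  v[c(sos + 1, sos + 12)] <- -1
  h <- timing_histograms(v, sos, eos)
  spr <- h$count[h$part == "spring"]
  expect_equal(spr[1:2], c(1L, 1L))
  expect_equal(sum(spr), 2)
  expect_equal(sum(h$count[h$part == "autumn"]), 0)

  # random year: bin sums equal the split counts
  set.seed(7)
  vr <- rnorm(365, 2, 4)
  hr <- timing_histograms(vr, 120, 280)
  sp <- split_counts(vr, 120, 280)
  expect_equal(sum(hr$count[hr$part == "spring"]), unname(sp["spr_fd"]))
  expect_equal(sum(hr$count[hr$part == "autumn"]), unname(sp["fal_fd"]))
  expect_identical(timing_histograms(rep(5, 365), 120, 280)$count,
                   c(rep(0L, 6), rep(0L, 11)))
})

test_that("vectorized counting matches the scalar day-loop oracle with the partition identity", {
  w <- small_world()
  set.seed(99)
  n_cases <- 400
  cases <- tibble::tibble(
    lat = sample(w$truth$lat, n_cases, replace = TRUE),
    lon = sample(w$truth$lon, n_cases, replace = TRUE),
    year = sample(w$tmin$years, n_cases, replace = TRUE),
    sos = sample(80:180, n_cases, replace = TRUE)
  )
  cases$eos <- cases$sos + sample(30:180, n_cases, replace = TRUE)
  cases$eos <- pmin(cases$eos, 365)
  for (mode in c("solstice", "midseason")) {
    fc <- frost_counts(w$daily, cases, cutoff_mode = mode)
    expect_equal(fc$gsfd, fc$spr_fd + fc$fal_fd)
    oracle <- vapply(seq_len(n_cases), function(r) {
      v <- daily_series(w$daily, cases$lat[r], cases$lon[r], cases$year[r])
      n <- 0L
      for (d in cases$sos[r]:cases$eos[r]) if (v[d] < 0) n <- n + 1L
      n
    }, integer(1))
    expect_equal(fc$gsfd, oracle)
    spl <- t(vapply(seq_len(n_cases), function(r) {
      v <- daily_series(w$daily, cases$lat[r], cases$lon[r], cases$year[r])
      split_counts(v, cases$sos[r], cases$eos[r], mode)
    }, c(spr_fd = 0L, fal_fd = 0L)))
    expect_equal(fc$spr_fd, unname(spl[, "spr_fd"]))
    expect_equal(fc$fal_fd, unname(spl[, "fal_fd"]))
  }
})

test_that("enlarging the window never decreases the frost count", {
  w <- small_world()
  set.seed(5)
  for (k in 1:60) {
    lat <- sample(w$truth$lat, 1); lon <- sample(w$truth$lon, 1)
    year <- sample(w$tmin$years, 1)
    v <- daily_series(w$daily, lat, lon, year)
    s <- sample(60:200, 1); e <- s + sample(20:150, 1)
    e <- min(e, 365)
    base <- count_frost_days(v, s, e)
    expect_gte(count_frost_days(v, max(s - sample(1:30, 1), 1), e), base)
    expect_gte(count_frost_days(v, s, min(e + sample(1:30, 1), 365)), base)
  }
})

test_that("missing phenology propagates to missing counts", {
  w <- small_world()
  ph <- w$phen[1:4, ]
  ph$sos[2] <- NA
  fc <- frost_counts(w$daily, ph)
  expect_true(is.na(fc$gsfd[2]))
  expect_false(anyNA(fc$gsfd[-2]))
})
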