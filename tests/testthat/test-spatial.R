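test_that("partial correlation matches limits and the residual-regression oracle", {
  set.seed(1)
  # independence limit: r_xy.z ~ r_xy for z independent of both
  x <- rnorm(4000); y <- 0.6 * x + rnorm(4000); z <- rnorm(4000)
  pc <- partial_correlation(x, y, z)
  expect_lt(abs(pc$r - cor(x, y)), 0.03)

  # y = x exactly: r = 1 regardless of a non-collinear z
  x2 <- rnorm(50)
  expect_equal(partial_correlation(x2, x2, rnorm(50))$r, 1)

  # residual-on-residual oracle at n = 200, to 1e-12
  for (k in 1:20) {
    z <- rnorm(200); x <- 0.5 * z + rnorm(200); y <- -0.7 * z + rnorm(200)
    pc <- partial_correlation(x, y, z)
    rx <- stats::residuals(stats::lm(x ~ z))
    ry <- stats::residuals(stats::lm(y ~ z))
    r_ref <- cor(rx, ry)
    expect_equal(pc$r, r_ref, tolerance = 1e-12)
    t_ref <- r_ref * sqrt(197 / (1 - r_ref^2))
    expect_equal(pc$p_value, 2 * stats::pt(-abs(t_ref), 197),
                 tolerance = 1e-10)
  }

  # degenerate inputs are missing
  expect_true(is.na(partial_correlation(rnorm(3), rnorm(3), rnorm(3))$r))
  z2 <- rnorm(30)
  expect_true(is.na(partial_correlation(z2, rnorm(30), z2)$r))
})

test_that("moving-window partials reproduce per-window oracles and coverage rules", {
  set.seed(2)
  lat <- 55 - 0.5 * (0:9); lon <- 10 + 0.5 * (0:11)
  px <- expand.grid(lat = lat, lon = lon)
  deltas <- tibble::tibble(
    lat = px$lat, lon = px$lon,
    delta_gsl = rnorm(nrow(px)),
    delta_tmin = rnorm(nrow(px))
  )
  # frost change exactly equals season-length change
  deltas$delta_gsfd <- deltas$delta_gsl
  pcm <- moving_window_partial(deltas)
  expect_true(all(abs(pcm$r_phen[!is.na(pcm$r_phen)] - 1) < 1e-8))

  # a random field: window at an interior cell equals the direct computation
  deltas$delta_gsfd <- rnorm(nrow(px))
  pcm2 <- moving_window_partial(deltas)
  ci <- 5; cj <- 6
  inwin <- abs(deltas$lat - lat[ci]) <= 1.0 + 1e-9 &
    abs(deltas$lon - lon[cj]) <= 1.0 + 1e-9
  ref <- partial_correlation(deltas$delta_gsl[inwin],
                             deltas$delta_gsfd[inwin],
                             deltas$delta_tmin[inwin])
  got <- dplyr::filter(pcm2, lat == !!lat[ci], lon == !!lon[cj])
  expect_equal(got$r_phen, ref$r, tolerance = 1e-12)
  expect_equal(got$p_phen, ref$p_value, tolerance = 1e-12)
  expect_equal(got$n_eff, 25)
  # exchangeability: the temperature coefficient is the same formula with
  # the (driver, control) roles swapped
  ref_t <- partial_correlation(deltas$delta_tmin[inwin],
                               deltas$delta_gsfd[inwin],
                               deltas$delta_gsl[inwin])
  expect_equal(got$r_temp, ref_t$r, tolerance = 1e-12)

  # windows below the pixel minimum are missing
  small <- dplyr::filter(deltas, lat > 54.9, lon < 11.1)  # 3 x 3 pixels
  pcm3 <- moving_window_partial(small, min_pixels = 10)
  expect_true(all(is.na(pcm3$r_phen)))
})

test_that("binned change density reports correct quadrant percentages", {
  d <- binned_change_density(rep(2.4, 50), rep(3.7, 50))
  expect_equal(nrow(d$density), 1)
  expect_equal(d$density$pct, 100)
  expect_equal(d$density$bin_phen, 2)
  expect_equal(d$quadrants$quadrant, "+phen/+fd")
  expect_equal(d$quadrants$pct, 100)

  set.seed(3)
  dp <- rnorm(4000); df_ <- rnorm(4000)
  d2 <- binned_change_density(dp, df_)
  expect_equal(sum(d2$quadrants$pct), 100)
  expect_true(all(abs(d2$quadrants$pct - 25) < 5))
  # counting oracle for one quadrant
  expect_equal(d2$quadrants$n[d2$quadrants$quadrant == "+phen/+fd"],
               sum(dp > 0 & df_ > 0))
})

test_that("continental association recovers slopes with weighted least squares", {
  lat <- runif(200, 35, 70)
  dgsl <- rnorm(200, 0, 2)
  d <- tibble::tibble(lat = lat, delta_gsl = dgsl,
                      delta_gsfd = 0.5 * dgsl)
  ca <- suppressWarnings(continental_association(d))  # exact fit warns
  expect_equal(ca$slope, 0.5, tolerance = 1e-9)
  expect_lt(ca$p_value, 1e-6)

  # normal-equations oracle with cos-latitude weights
  set.seed(4)
  d$delta_gsfd <- 0.3 * d$delta_gsl + rnorm(200)
  ca2 <- continental_association(d)
  w <- cos(d$lat * pi / 180)
  xm <- sum(w * d$delta_gsl) / sum(w); ym <- sum(w * d$delta_gsfd) / sum(w)
  b_ref <- sum(w * (d$delta_gsl - xm) * (d$delta_gsfd - ym)) /
    sum(w * (d$delta_gsl - xm)^2)
  expect_equal(ca2$slope, b_ref, tolerance = 1e-10)

  # independent fields: slope statistically indistinguishable from zero
  d$delta_gsfd <- rnorm(200)
  ca3 <- continental_association(d)
  expect_lt(abs(ca3$slope), 4 * ca3$se)
})
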