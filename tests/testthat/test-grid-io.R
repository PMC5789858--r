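test_that("cubes round-trip bit-exactly through the text format", {
  tr <- gen_truth(2, 3, seed = 5)
  tm <- gen_tmin(tr, 2000:2001, timestep_hours = 6, seed = 6)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cube(tm, p)
  tm2 <- read_cube(p)
  expect_identical(tm2$values, tm$values)
  expect_identical(tm2$lat, tm$lat)
  expect_identical(tm2$timestep_hours, tm$timestep_hours)

  nd <- gen_ndvi(tr, 2000:2001, noise_sd = 0.02, seed = 7)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cube(nd, p2)
  nd2 <- read_cube(p2)
  expect_identical(nd2$values, nd$values)
  expect_identical(nd2$composite_doy, nd$composite_doy)
})

test_that("a cube file without a latitude axis fails naming the axis", {
  tr <- gen_truth(1, 2, seed = 1)
  tm <- gen_tmin(tr, 2000, timestep_hours = 6, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cube(tm, p)
  lines <- readLines(p)
  writeLines(lines[!grepl("^#lat=", lines)], p)
  expect_error(read_cube(p), "lat")
})

test_that("leap-day samples are dropped so every year has 365 days", {
  tr <- gen_truth(1, 1, constant_ranges(), seed = 1)
  tm <- gen_tmin(tr, 2000, timestep_hours = 6, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cube(tm, p)
  # splice a Feb 29 (day 60) into the body, renumbering later days as a
  # 366-day year would
  body <- readr::read_csv(p, comment = "#", show_col_types = FALSE)
  body$p1 <- seq_len(nrow(body)) / 1000  # distinctive values: sample index
  leap <- body
  leap$doy <- ifelse(leap$doy >= 60, leap$doy + 1L, leap$doy)
  feb29 <- leap[leap$doy == 59, ]
  feb29$doy <- 60L
  feb29$p1 <- -999                       # the sample that must disappear
  leap <- dplyr::arrange(dplyr::bind_rows(leap, feb29), doy, hour)
  hdr <- grep("^#", readLines(p), value = TRUE)
  writeLines(hdr, p)
  readr::write_csv(leap, p, append = TRUE, col_names = TRUE)
  cube <- read_cube(p)
  expect_equal(dim(cube$values)[2], 365L)
  expect_false(any(cube$values == -999))
  # days after Feb 29 are renumbered: last sample of the year is retained
  expect_equal(max(cube$values), nrow(body) / 1000)
})

test_that("Kelvin input is auto-detected and converted", {
  tr <- gen_truth(1, 1, constant_ranges(tmin_annual_mean = 5), seed = 1)
  tm <- gen_tmin(tr, 2000, timestep_hours = 6, seed = 1)
  tm$values <- tm$values + 273.15
  p <- withr::local_tempfile(fileext = ".csv")
  write_cube(tm, p)
  expect_warning(cube <- read_cube(p), "Kelvin")
  expect_equal(as.vector(cube$values), rep(5, 4 * 365), tolerance = 1e-9)
  expect_equal(cube$units, "degC")
})

test_that("phenology remap block-averages with a 50% coverage rule", {
  # 12 x 12 fine cells at 1/12 degree -> 2 x 2 coarse cells at 0.5 degree
  fine_res <- 0.5 / 6
  lat <- 50 - fine_res * (0:11)
  lon <- 10 + fine_res * (0:11)
  px <- expand.grid(lat = lat, lon = lon)
  phen <- tibble::tibble(lat = px$lat, lon = px$lon, year = 2000,
                         method = "ensemble", sos = 120, eos = 280,
                         gsl = 160)
  out <- remap_phenology(phen, 0.5)
  expect_equal(nrow(out), 4)
  expect_true(all(out$sos == 120))
  expect_true(all(out$gsl == 160))

  # one block with 35 of 36 cells missing -> coarse cell missing
  phen2 <- phen
  in_block <- phen2$lat > 50 - 6 * fine_res + 1e-9 & phen2$lon < 10 + 6 * fine_res - 1e-9
  drop <- which(in_block)[-1]
  phen2$sos[drop] <- NA
  phen2$eos[drop] <- NA
  out2 <- remap_phenology(phen2, 0.5)
  blk <- out2[which.max(out2$lat * (out2$lon == min(out2$lon))), ]
  top_left <- dplyr::filter(out2, lat == max(lat), lon == min(lon))
  expect_true(is.na(top_left$sos))

  # random field: coarse value equals the hand-computed block mean
  set.seed(42)
  phen3 <- phen
  phen3$sos <- round(runif(nrow(phen3), 100, 140))
  phen3$eos <- phen3$sos + 150
  out3 <- remap_phenology(phen3, 0.5)
  blk_cells <- phen3$lat > 50 - 6 * fine_res + 1e-9 &
    phen3$lon < 10 + 6 * fine_res - 1e-9
  expect_equal(
    dplyr::filter(out3, lat == max(lat), lon == min(lon))$sos,
    mean(phen3$sos[blk_cells])
  )

  # identity remap is idempotent
  expect_equal(nrow(remap_phenology(phen, fine_res)), nrow(phen))
  expect_error(remap_phenology(phen, 0.2), "integer multiple")
})

test_that("site tables round-trip and malformed rows are located", {
  tr <- gen_truth(2, 2, seed = 3)
  tab <- gen_insitu(tr, 10, 2000:2005, seed = 4)
  p <- withr::local_tempfile(fileext = ".csv")
  write_site_table(tab, p)
  expect_equal(read_site_table(p), tab)

  lines <- readLines(p)
  lines[3] <- sub("^(([^,]*,){4})[^,]*", "\\1abc", lines[3])
  writeLines(lines, p)
  expect_error(read_site_table(p), "line\\(s\\) 3")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,lat,lon,year,unfold_doy,senesce_doy",
               "S1,48.5,9.25,1995,101,290",
               "S1,48.5,9.25,1996,,285",
               "S2,47.5,11.75,1995,130,270"), p2)
  tab2 <- read_site_table(p2)
  expect_equal(tab2$unfold_doy, c(101L, NA, 130L))
  expect_equal(tab2$lat, c(48.5, 48.5, 47.5))
})
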