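test_that("Baskerville-Emin growing degrees match the direct cases and the sine integral", {
  expect_equal(daily_growing_degrees(12, 20, 10), 6)
  expect_equal(daily_growing_degrees(2, 8, 10), 0)
  # crossing case: single-sine quadrature oracle
  tmin <- 4; tmax <- 16; base <- 10
  m <- (tmin + tmax) / 2; w <- (tmax - tmin) / 2
  f <- function(t) pmax(m + w * sin(2 * pi * t) - base, 0)
  oracle <- stats::integrate(f, 0, 1, subdivisions = 2000L,
                             rel.tol = 1e-10)$value
  expect_equal(daily_growing_degrees(tmin, tmax, base), oracle,
               tolerance = 1e-3)
  # continuity across the base-crossing boundary
  eps <- 1e-7
  expect_equal(daily_growing_degrees(10 - eps, 20, 10),
               daily_growing_degrees(10 + eps, 20, 10), tolerance = 1e-5)
  expect_equal(daily_growing_degrees(2, 10 + eps, 10),
               daily_growing_degrees(2, 10 - eps, 10), tolerance = 1e-5)
  expect_error(daily_growing_degrees(20, 10), "tmin")
})

test_that("day length behaves at the equator, equinox, and matches solar geometry", {
  expect_true(all(abs(day_length(0, c(1, 100, 200, 355)) - 12) < 0.2))
  expect_equal(day_length(45, 80), 12, tolerance = 0.3)
  # independent solar-geometry oracle (Cooper declination + hour angle)
  lat <- 45; doy <- 172
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  ws <- acos(-tan(lat * pi / 180) * tan(decl))
  expect_equal(day_length(lat, doy), 2 * ws * 24 / (2 * pi),
               tolerance = 0.05)
  expect_error(day_length(70, 100), "polar")
})

test_that("photothermal time is the product of growing degrees and day length", {
  expect_equal(photothermal_time(0, 14), 0)
  expect_equal(photothermal_time(6, 15), 90)
  gdd <- c(3, 7, 11); dl <- c(13, 14, 15)
  expect_equal(sum(photothermal_time(gdd, dl)),
               photothermal_time(gdd[1], dl[1]) +
                 photothermal_time(gdd[2], dl[2]) +
                 photothermal_time(gdd[3], dl[3]))
  expect_error(photothermal_time(-1, 12), "nonnegative")
})

test_that("vapor pressure deficit follows the Tetens relation", {
  expect_equal(vapor_pressure_deficit(15, 25, 100), 0)
  es <- (0.6108 * exp(17.27 * 25 / (25 + 237.3)) +
           0.6108 * exp(17.27 * 15 / (15 + 237.3))) / 2
  expect_equal(vapor_pressure_deficit(15, 25, 0), es, tolerance = 1e-10)
  expect_equal(vapor_pressure_deficit(15, 25, 60), es * 0.4,
               tolerance = 1e-3)
  expect_error(vapor_pressure_deficit(15, 25, 130), "humidity")
})

test_that("FAO-56 reference evapotranspiration matches an independent implementation", {
  # independently coded FAO-56 steps for a mid-summer temperate day
  tmin <- 14; tmax <- 28; rh <- 55; srad <- 26; u2 <- 2.2
  lat <- 43; z <- 250; doy <- 195
  svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (svp(tmax) + svp(tmin)) / 2
  ea <- es * rh / 100
  tm <- (tmax + tmin) / 2
  slope <- 4098 * svp(tm) / (tm + 237.3)^2
  press <- 101.3 * ((293 - 0.0065 * z) / 293)^5.26
  psy <- 0.000665 * press
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  omega <- acos(-tan(phi) * tan(dec))
  ra <- 24 * 60 / pi * 0.082 * dr *
    (omega * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(omega))
  rso <- (0.75 + 2e-5 * z) * ra
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * srad / rso - 0.35)
  rn <- 0.77 * srad - rnl
  ref <- (0.408 * slope * rn + psy * 900 / (tm + 273) * u2 * (es - ea)) /
    (slope + psy * (1 + 0.34 * u2))
  got <- et0_fao56(tmin, tmax, rh, srad, u2, lat, z, doy)
  expect_equal(got, ref, tolerance = 0.05)
  expect_true(got > 3 && got < 9)  # plausible range for such a day
  # monotone in wind when vpd > 0
  winds <- seq(0.5, 6, by = 0.5)
  et <- et0_fao56(tmin, tmax, rh, srad, winds, lat, z, doy)
  expect_true(all(diff(et) >= 0))
})

test_that("daily water balance is the signed difference and accumulates", {
  expect_equal(daily_water_balance(10, 4), 6)
  expect_equal(daily_water_balance(0, 5), -5)
  p <- c(0, 12, 3); e <- c(4, 5, 6)
  expect_equal(sum(daily_water_balance(p, e)), sum(p) - sum(e))
})

make_subdaily <- function(dates, tmin = 12, tmax = 24, prcp = 6, rh = 60,
                          srad_mj = 20, wind = 2) {
  hrs <- seq(0, 23.5, by = 0.5)
  recs <- lapply(dates, function(d) {
    temp <- (tmin + tmax) / 2 + (tmax - tmin) / 2 *
      cos(2 * pi * (hrs - 14) / 24)
    rain <- rep(0, 48); rain[c(10, 20)] <- prcp / 2
    srad_w <- srad_mj * 1e6 / 86400 * (1 + 0.5 * cos(2 * pi * (hrs - 12) / 24))
    ts <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") + hrs * 3600
    data.frame(site = "S1", timestamp = rep(ts, 5),
               variable = rep(c("temperature", "rh", "rainfall", "srad",
                                "wind"), each = 48),
               value = c(temp, rep(rh, 48) + sin(hrs), rain, srad_w,
                         rep(wind, 48) + 0.1 * cos(hrs)))
  })
  do.call(rbind, recs)
}

test_that("daily aggregation summarises clean records without flags", {
  recs <- make_subdaily(as.Date("2015-07-01") + 0:2)
  d <- qc_aggregate_daily(recs)
  expect_equal(nrow(d), 3)
  expect_false(any(d$flag_count | d$flag_range | d$flag_persistence |
                     d$flag_consistency))
  expect_equal(d$tmax[1], 24, tolerance = 0.01)
  expect_equal(d$tmin[1], 12, tolerance = 0.01)
  expect_equal(d$tmean, (d$tmax + d$tmin) / 2)
  expect_equal(d$prcp[1], 6)
  expect_equal(d$srad[1], 20, tolerance = 0.01)
})

test_that("QC flags stuck sensors, gaps and out-of-range spikes", {
  recs <- make_subdaily(as.Date("2015-07-01") + 0:1)
  day2 <- as.Date(recs$timestamp, tz = "UTC") == as.Date("2015-07-02")
  # stuck temperature sensor on day 2
  recs$value[day2 & recs$variable == "temperature"] <- 18
  d <- qc_aggregate_daily(recs)
  expect_true(d$flag_persistence[2])
  expect_true(is.na(d$tmax[2]))
  expect_false(d$flag_persistence[1])
  expect_false(is.na(d$tmax[1]))
  # gap: drop most of day 1's rh records
  recs2 <- make_subdaily(as.Date("2015-07-01"))
  rh_rows <- which(recs2$variable == "rh")
  recs2 <- recs2[-rh_rows[1:20], ]
  d2 <- qc_aggregate_daily(recs2)
  expect_true(d2$flag_count[1])
  expect_true(is.na(d2$rh[1]))
  # spike beyond the physical range
  recs3 <- make_subdaily(as.Date("2015-07-01"))
  i <- which(recs3$variable == "temperature")[5]
  recs3$value[i] <- 80
  d3 <- qc_aggregate_daily(recs3)
  expect_true(d3$flag_range[1])
  expect_true(is.na(d3$tmax[1]))
})

test_that("inverse-distance gap filling weights neighbours by d^-power", {
  base <- constant_daily(as.Date("2015-07-01") + 0:4)
  base$site <- "T"
  base$flag_imputed <- FALSE
  target <- base
  target$tmax[3] <- NA
  nb1 <- base; nb1$tmax <- 10
  nb2 <- base; nb2$tmax <- 20
  one <- fill_gaps_idw(target, list(list(series = nb1, distance = 5)))
  expect_equal(one$tmax[3], 10)
  expect_true(one$flag_imputed[3])
  expect_equal(one$tmax[-3], target$tmax[-3])  # observed untouched
  two <- fill_gaps_idw(target, list(list(series = nb1, distance = 7),
                                    list(series = nb2, distance = 7)))
  expect_equal(two$tmax[3], 15)
  nb3 <- base; nb3$tmax <- 31
  three <- fill_gaps_idw(target,
                         list(list(series = nb1, distance = 2),
                              list(series = nb2, distance = 4),
                              list(series = nb3, distance = 8)))
  w <- c(2, 4, 8)^-2
  expect_equal(three$tmax[3], sum(c(10, 20, 31) * w) / sum(w))
})

test_that("the QC summary reports per-site flag counts", {
  d <- constant_daily(as.Date("2015-07-01") + 0:3)
  d$site <- "S1"
  d$flag_count <- FALSE; d$flag_range <- FALSE
  d$flag_persistence <- c(TRUE, FALSE, FALSE, TRUE)
  d$flag_consistency <- FALSE; d$flag_imputed <- c(FALSE, TRUE, FALSE, FALSE)
  path <- tempfile(fileext = ".json")
  s <- write_qc_summary(d, path)
  expect_equal(s$S1$persistence, 2)
  expect_equal(s$S1$imputed, 1)
  expect_equal(s$S1$days, 4)
  back <- jsonlite::read_json(path)
  expect_equal(back$S1$persistence, 2)
  unlink(path)
})
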