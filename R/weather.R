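#' Default quality-control configuration for station records
#'
#' Range limits follow common operational QC guidance for mid-latitude
#' agricultural stations; all values are configurable.
#'
#' @param temperature_range,rh_range,wind_range,rain_range,srad_range numeric
#'   length-2 vectors of plausible physical limits per sub-daily record.
#'   Rain and solar limits apply to daily accumulations.
#' @param min_frac minimum fraction of the nominal sub-daily cadence that must
#'   be present and valid for a day to escape the record-count flag.
#' @param nominal_per_day nominal number of sub-daily records per day
#'   (48 for a 30-minute cadence).
#' @return A list of QC rule parameters.
#' @export
qc_config <- function(temperature_range = c(-40, 50),
                      rh_range = c(0, 100),
                      wind_range = c(0, 40),
                      rain_range = c(0, 300),
                      srad_range = c(0, 1500),
                      min_frac = 0.8,
                      nominal_per_day = 48L) {
  list(
    ranges = list(temperature = temperature_range, rh = rh_range,
                  wind = wind_range, rainfall = rain_range, srad = srad_range),
    min_frac = min_frac,
    nominal_per_day = as.integer(nominal_per_day)
  )
}

.wx_vars <- c("temperature", "rh", "rainfall", "srad", "wind")

#' Quality-control and aggregate sub-daily station records to daily values
#'
#' Applies record-count, range, persistence and internal-consistency tests to
#' 30-minute station records and summarises them per day: temperature to daily
#' minimum/maximum with the daily mean taken as `(tmin + tmax)/2`, rainfall
#' summed, relative humidity and wind averaged, and solar radiation
#' accumulated to MJ m-2 day-1 (mean power times 86400 s). Days failing a
#' test carry the corresponding flag and the affected variables are set
#' missing; values that pass are never altered.
#'
#' @param records data.frame with columns `site`, `timestamp` (POSIXct or
#'   ISO-8601 string), `variable` (one of `temperature`, `rh`, `rainfall`,
#'   `srad` in W/m2, `wind`) and `value`. A single site.
#' @param rules list from [qc_config()].
#' @return data.frame with one row per day: `site`, `date`, `tmax`, `tmin`,
#'   `tmean`, `prcp`, `rh`, `srad`, `wind` and logical flag columns
#'   `flag_count`, `flag_range`, `flag_persistence`, `flag_consistency`,
#'   `flag_imputed`.
#' @export
qc_aggregate_daily <- function(records, rules = qc_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty sub-daily record set")
  if (length(unique(records$site)) > 1L)
    stop("qc_aggregate_daily() expects records from a single site")
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  day <- as.Date(ts, tz = "UTC")
  dates <- sort(unique(day))
  out <- data.frame(
    site = records$site[1], date = dates,
    tmax = NA_real_, tmin = NA_real_, tmean = NA_real_,
    prcp = NA_real_, rh = NA_real_, srad = NA_real_, wind = NA_real_,
    flag_count = FALSE, flag_range = FALSE, flag_persistence = FALSE,
    flag_consistency = FALSE, flag_imputed = FALSE,
    stringsAsFactors = FALSE
  )
  min_n <- ceiling(rules$min_frac * rules$nominal_per_day)
  for (i in seq_along(dates)) {
    sel <- day == dates[i]
    for (v in .wx_vars) {
      vv <- records$value[sel & records$variable == v]
      vv <- vv[is.finite(vv)]
      rng <- rules$ranges[[v]]
      n_ok <- length(vv)
      if (v %in% c("temperature", "rh", "wind")) {
        bad_range <- n_ok > 0 && any(vv < rng[1] | vv > rng[2])
      } else bad_range <- FALSE
      bad_count <- n_ok < min_n
      # persistence: zero variability over a full day of a continuous variable
      bad_persist <- v %in% c("temperature", "rh", "wind", "srad") &&
        n_ok >= min_n && stats::var(vv) == 0
      if (bad_count) out$flag_count[i] <- TRUE
      if (bad_range) out$flag_range[i] <- TRUE
      if (bad_persist) out$flag_persistence[i] <- TRUE
      if (bad_count || bad_range || bad_persist) next
      switch(v,
        temperature = {
          out$tmax[i] <- max(vv); out$tmin[i] <- min(vv)
          out$tmean[i] <- (out$tmax[i] + out$tmin[i]) / 2
        },
        rh = out$rh[i] <- mean(vv),
        rainfall = out$prcp[i] <- sum(vv),
        srad = out$srad[i] <- mean(vv) * 86400 / 1e6,
        wind = out$wind[i] <- mean(vv)
      )
    }
    # internal consistency after aggregation
    bad_cons <- FALSE
    if (!is.na(out$tmin[i]) && !is.na(out$tmax[i]) && out$tmin[i] > out$tmax[i])
      bad_cons <- TRUE
    if (!is.na(out$prcp[i]) &&
        (out$prcp[i] < rules$ranges$rainfall[1] ||
         out$prcp[i] > rules$ranges$rainfall[2])) {
      out$flag_range[i] <- TRUE; out$prcp[i] <- NA_real_
    }
    if (bad_cons) {
      out$flag_consistency[i] <- TRUE
      out$tmax[i] <- out$tmin[i] <- out$tmean[i] <- NA_real_
    }
  }
  out
}

#' Fill missing daily values by inverse-distance weighting
#'
#' Missing entries of the target series are replaced by the
#' distance-weighted mean (weights proportional to `distance^-power`) of the
#' neighbouring stations' values for the same date. Observed values are never
#' touched; filled days receive the `imputed` flag. Days no neighbour covers
#' stay missing.
#'
#' @param target daily series as returned by [qc_aggregate_daily()].
#' @param neighbors list of `list(series = <daily data.frame>, distance = km)`.
#' @param power inverse-distance exponent (2 = inverse squared distance).
#' @return The target series with gaps filled where possible.
#' @export
fill_gaps_idw <- function(target, neighbors, power = 2) {
  stopifnot(length(neighbors) >= 1L)
  vars <- c("tmax", "tmin", "tmean", "prcp", "rh", "srad", "wind")
  for (i in seq_len(nrow(target))) {
    d <- target$date[i]
    for (v in vars) {
      if (!is.na(target[[v]][i])) next
      vals <- numeric(0); wts <- numeric(0)
      for (nb in neighbors) {
        j <- match(d, nb$series$date)
        if (is.na(j)) next
        x <- nb$series[[v]][j]
        if (is.na(x)) next
        vals <- c(vals, x); wts <- c(wts, nb$distance^(-power))
      }
      if (length(vals)) {
        target[[v]][i] <- sum(vals * wts) / sum(wts)
        target$flag_imputed[i] <- TRUE
      }
    }
  }
  target
}

#' Daily growing degrees (Baskerville-Emin single-sine method)
#'
#' Thermal time accumulated above a base temperature. When the whole diurnal
#' range sits above the base the estimate is `(tmin + tmax)/2 - base`; when
#' entirely below it is zero; when the sine curve crosses the base, the
#' single-sine integral above the base is used.
#'
#' @param tmin,tmax daily minimum and maximum temperature (degrees C),
#'   vectorised.
#' @param base base temperature (degrees C), default 10 for maize.
#' @return growing degrees (degree C day).
#' @export
daily_growing_degrees <- function(tmin, tmax, base = 10) {
  if (any(tmin > tmax, na.rm = TRUE)) stop("tmin > tmax")
  m <- (tmin + tmax) / 2
  w <- (tmax - tmin) / 2
  gd <- ifelse(tmin >= base, m - base, 0)
  cross <- tmin < base & tmax > base
  cross[is.na(cross)] <- FALSE
  if (any(cross)) {
    theta <- asin(pmin(pmax((base - m[cross]) / w[cross], -1), 1))
    gd[cross] <- ((m[cross] - base) * (pi / 2 - theta) +
                    w[cross] * cos(theta)) / pi
  }
  gd
}

#' Astronomical day length
#'
#' Day length in hours from solar declination; polar latitudes, where
#' day-long light or darkness occurs, are not supported.
#'
#' @param latitude degrees, `|latitude| < 66.5`.
#' @param day_of_year integer day of year (1-366), vectorised.
#' @return hours of daylight, in (0, 24).
#' @export
day_length <- function(latitude, day_of_year) {
  if (abs(latitude) >= 66.5)
    stop("polar latitudes (|lat| >= 66.5) are not supported")
  decl <- 0.409 * sin(2 * pi / 365 * day_of_year - 1.39)
  phi <- latitude * pi / 180
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  24 / pi * ws
}

#' Photothermal time
#'
#' Product of the daily growing degrees and the day length in hours.
#'
#' @param gdd daily growing degrees (>= 0).
#' @param daylen day length in hours.
#' @return photothermal time (degree C day hours).
#' @export
photothermal_time <- function(gdd, daylen) {
  if (any(gdd < 0, na.rm = TRUE)) stop("gdd must be nonnegative")
  gdd * daylen
}

# Tetens saturation vapour pressure (kPa) at temperature T (degrees C)
sat_vp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

#' Mean daily vapor pressure deficit
#'
#' Saturation vapour pressure is the mean of the Tetens values at the daily
#' maximum and minimum temperature; actual vapour pressure is derived from
#' mean relative humidity.
#'
#' @param tmin,tmax daily temperature extremes (degrees C).
#' @param rh_mean mean daily relative humidity (percent, 0-100).
#' @return vapour pressure deficit (kPa), nonnegative.
#' @export
vapor_pressure_deficit <- function(tmin, tmax, rh_mean) {
  if (any(rh_mean < 0 | rh_mean > 100, na.rm = TRUE))
    stop("relative humidity must lie in [0, 100]")
  es <- (sat_vp(tmax) + sat_vp(tmin)) / 2
  ea <- es * rh_mean / 100
  pmax(es - ea, 0)
}

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily grass-reference ET with soil heat flux zero, net shortwave from the
#' measured solar radiation (albedo 0.23), the FAO net-longwave term with
#' clear-sky radiation from extraterrestrial radiation, and the psychrometric
#' constant from elevation-derived atmospheric pressure. Wind speed is
#' assumed measured at 2 m; `wind_height` applies the FAO logarithmic profile
#' correction for other sensor heights.
#'
#' @param tmin,tmax daily temperature extremes (degrees C).
#' @param rh_mean mean daily relative humidity (percent).
#' @param srad daily incoming solar radiation (MJ m-2 day-1).
#' @param wind mean daily wind speed (m/s).
#' @param latitude site latitude (degrees).
#' @param elevation site elevation (m).
#' @param doy day of year.
#' @param wind_height height of the wind measurement (m), default 2.
#' @return reference evapotranspiration (mm/day), nonnegative; `NA` when any
#'   required input is missing.
#' @export
et0_fao56 <- function(tmin, tmax, rh_mean, srad, wind, latitude, elevation,
                      doy, wind_height = 2) {
  n <- max(length(tmin), length(tmax), length(doy))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  rh_mean <- rep_len(rh_mean, n); srad <- rep_len(srad, n)
  wind <- rep_len(wind, n); doy <- rep_len(doy, n)
  u2 <- if (wind_height == 2) wind else
    wind * 4.87 / log(67.8 * wind_height - 5.42)
  tmean <- (tmin + tmax) / 2
  delta <- 4098 * sat_vp(tmean) / (tmean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * pressure
  es <- (sat_vp(tmax) + sat_vp(tmin)) / 2
  ea <- es * rh_mean / 100
  # extraterrestrial radiation
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * srad
  rel <- ifelse(rso > 0, pmin(pmax(srad / rso, 0), 1), 0)
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl
  et0 <- (0.408 * delta * rn + gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
  pmax(et0, 0)
}

#' Daily water balance
#'
#' Difference between water input (precipitation plus irrigation) and the
#' reference evapotranspiration; may be negative.
#'
#' @param precip_plus_irrigation mm/day.
#' @param et0 reference evapotranspiration, mm/day.
#' @return mm/day.
#' @export
daily_water_balance <- function(precip_plus_irrigation, et0) {
  precip_plus_irrigation - et0
}

#' Append derived daily variables to a daily weather series
#'
#' Adds growing degrees, day length, photothermal time, vapour pressure
#' deficit, FAO-56 reference evapotranspiration and the daily water balance.
#' Irrigation, when present as an `irrigation` column, is added to
#' precipitation for the water-input variables.
#'
#' @param daily daily weather data.frame (`date`, `tmax`, `tmin`, `tmean`,
#'   `prcp`, `rh`, `srad`, `wind`, optional `irrigation`).
#' @param latitude,elevation site metadata.
#' @param base base temperature for growing degrees (degrees C).
#' @return the input with columns `water_in`, `gdd`, `daylen`, `ptt`, `vpd`,
#'   `et0`, `wbal` appended.
#' @export
derive_daily <- function(daily, latitude, elevation, base = 10) {
  doy <- as.integer(strftime(daily$date, "%j"))
  irr <- if ("irrigation" %in% names(daily)) daily$irrigation else 0
  daily$water_in <- daily$prcp + irr
  daily$gdd <- daily_growing_degrees(daily$tmin, daily$tmax, base)
  daily$daylen <- day_length(latitude, doy)
  daily$ptt <- photothermal_time(daily$gdd, daily$daylen)
  daily$vpd <- vapor_pressure_deficit(daily$tmin, daily$tmax, daily$rh)
  daily$et0 <- et0_fao56(daily$tmin, daily$tmax, daily$rh, daily$srad,
                         daily$wind, latitude, elevation, doy)
  daily$wbal <- daily_water_balance(daily$water_in, daily$et0)
  daily
}

#' Write a QC summary report
#'
#' Counts of flagged days per rule and per site, written as JSON.
#'
#' @param daily daily weather series (one or more sites) with flag columns.
#' @param path output path; `NULL` returns the summary list invisibly
#'   without writing.
#' @return the summary list, invisibly.
#' @export
write_qc_summary <- function(daily, path = NULL) {
  flags <- c("flag_count", "flag_range", "flag_persistence",
             "flag_consistency", "flag_imputed")
  summ <- lapply(split(daily, daily$site), function(d) {
    c(list(days = nrow(d)),
      stats::setNames(lapply(flags, function(f) sum(d[[f]])),
                      sub("flag_", "", flags)))
  })
  if (!is.null(path))
    jsonlite::write_json(summ, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(summ)
}
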