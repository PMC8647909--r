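#' Registry of environmental covariate names
#'
#' Thirteen weather-based covariates per growth stage (suffixes `.V`
#' vegetative, `.F` flowering, `.G` grain filling) plus four soil covariates.
#'
#' @param trait `"grain_yield"` uses all three stages; `"plant_height"`
#'   excludes the grain-filling weather covariates, since plant height is
#'   measured shortly after flowering.
#' @param coords whether the longitude/latitude columns are included.
#' @return character vector of column names in registry order.
#' @export
ec_covariate_names <- function(trait = c("grain_yield", "plant_height"),
                               coords = FALSE) {
  trait <- match.arg(trait)
  base <- c("P", "FreqP5", "MeanT", "MinT", "MaxT", "GDD", "Photothermal.Time",
            "FreqMaxT30", "FreqMaxT35", "St30", "CumSumET0",
            "CumDailyWaterBalance", "Sdrad")
  stages <- c("V", "F", "G")
  if (trait == "plant_height") stages <- c("V", "F")
  weather <- as.vector(vapply(stages, function(s) paste0(base, ".", s),
                              character(length(base))))
  soil <- c("SandProp.SC", "Silt.Prop.SC", "ClayProp.SC", "OM.SC")
  out <- c(weather, soil)
  if (coords) out <- c(out, "longitude", "latitude")
  out
}

#' Growth-stage windows for one hybrid in one environment
#'
#' Three non-overlapping, contiguous, half-open day intervals anchored on the
#' planting and 50 percent silking dates: vegetative from planting to one
#' week before silking, flowering from one week before to two weeks after
#' silking (approximately the pollination period), and grain filling for the
#' 65 days after the flowering window, by which time physiological maturity
#' is normally reached.
#'
#' @param planting,silking `Date` scalars; silking must be at least 8 days
#'   after planting so the vegetative window is nonempty.
#' @return list with `Date` bounds `veg_start`, `veg_end`, `flw_end`,
#'   `gf_end`; each window is `[start, end)`.
#' @export
stage_windows <- function(planting, silking) {
  planting <- as.Date(planting); silking <- as.Date(silking)
  if (as.numeric(silking - planting) < 8)
    stop(sprintf("silking (%s) less than 8 days after planting (%s)",
                 format(silking), format(planting)))
  list(veg_start = planting,
       veg_end = silking - 7,
       flw_end = silking + 14,
       gf_end = silking + 14 + 65)
}

.window_covs <- function(d, suffix) {
  n_days <- nrow(d)
  st30_days <- d$tmax > 30
  out <- c(
    P = sum(d$water_in),
    FreqP5 = mean(d$water_in > 5),
    MeanT = mean(d$tmean),
    MinT = mean(d$tmin),
    MaxT = mean(d$tmax),
    GDD = sum(d$gdd),
    Photothermal.Time = sum(d$ptt),
    FreqMaxT30 = mean(d$tmax > 30),
    FreqMaxT35 = mean(d$tmax > 35),
    St30 = sum(d$tmax[st30_days]),
    CumSumET0 = sum(d$et0),
    CumDailyWaterBalance = sum(d$wbal),
    Sdrad = sum(d$srad)
  )
  names(out) <- paste0(names(out), ".", suffix)
  out
}

#' Stage-wise weather covariates for one hybrid-environment observation
#'
#' Computes the 13 weather-based covariates for each of the three growth
#' windows from a derived daily series (see [derive_daily()]): accumulated
#' water input, frequency of days with more than 5 mm water, means of daily
#' mean/minimum/maximum temperature, cumulative growing degree days and
#' photothermal time, frequencies of days with maximum temperature above 30
#' and above 35 degrees C, the sum of daily maxima above 30 degrees C,
#' accumulated reference evapotranspiration, cumulative daily water balance,
#' and accumulated solar radiation. Frequencies are fractions of window days
#' so windows of different length are comparable; thresholds are strict.
#'
#' @param daily derived daily series covering all three windows, no gaps in
#'   the required variables.
#' @param windows output of [stage_windows()].
#' @return named numeric vector of 39 covariates (13 x stages V, F, G).
#' @export
stage_covariates <- function(daily, windows) {
  req <- c("water_in", "tmean", "tmin", "tmax", "gdd", "ptt", "et0", "wbal",
           "srad")
  dates <- seq(windows$veg_start, windows$gf_end - 1, by = "day")
  idx <- match(dates, daily$date)
  if (anyNA(idx))
    stop("daily series does not cover the growth windows; missing days: ",
         paste(format(dates[is.na(idx)][seq_len(min(5, sum(is.na(idx))))]),
               collapse = ", "))
  d <- daily[idx, , drop = FALSE]
  bad <- !stats::complete.cases(d[req])
  if (any(bad))
    stop("flagged/missing weather values inside growth windows on: ",
         paste(format(d$date[bad][seq_len(min(5, sum(bad)))]), collapse = ", "))
  cut1 <- d$date < windows$veg_end
  cut2 <- d$date >= windows$veg_end & d$date < windows$flw_end
  cut3 <- d$date >= windows$flw_end
  c(.window_covs(d[cut1, ], "V"), .window_covs(d[cut2, ], "F"),
    .window_covs(d[cut3, ], "G"))
}

#' Assemble the environmental covariate matrix W
#'
#' Stacks the per-observation stage covariates with the four soil covariates
#' (and optionally longitude/latitude), applies the trait's column mask
#' (plant height drops grain-filling weather columns), removes zero-variance
#' columns with a warning, and centers and standardizes each column. The
#' centering/scaling statistics can be computed on a training subset only and
#' applied to all rows, which is what honest forward prediction requires.
#'
#' @param stage_covs matrix (observations x 39) from [stage_covariates()],
#'   rows named or aligned with `soil_site`.
#' @param soil data.frame with columns `site`, `SandProp.SC`, `Silt.Prop.SC`,
#'   `ClayProp.SC`, `OM.SC` (one row per site).
#' @param soil_site character vector: site of each observation.
#' @param coords optional data.frame/matrix with per-observation `longitude`
#'   and `latitude`; `NULL` to omit.
#' @param trait `"grain_yield"` or `"plant_height"`.
#' @param standardize center and scale columns (default `TRUE`).
#' @param train_index rows used to compute the standardization statistics
#'   (default: all rows).
#' @return numeric matrix with attributes `center` and `scale`; class
#'   `"ec_matrix"`.
#' @export
assemble_W <- function(stage_covs, soil, soil_site, coords = NULL,
                       trait = c("grain_yield", "plant_height"),
                       standardize = TRUE, train_index = NULL) {
  trait <- match.arg(trait)
  stage_covs <- as.matrix(stage_covs)
  j <- match(soil_site, soil$site)
  if (anyNA(j))
    stop("missing soil profile for site(s): ",
         paste(unique(soil_site[is.na(j)]), collapse = ", "))
  soil_cols <- as.matrix(soil[j, c("SandProp.SC", "Silt.Prop.SC",
                                   "ClayProp.SC", "OM.SC")])
  rownames(soil_cols) <- NULL
  W <- cbind(stage_covs, soil_cols)
  if (!is.null(coords)) {
    coords <- as.matrix(coords[, c("longitude", "latitude")])
    W <- cbind(W, coords)
  }
  keep_names <- ec_covariate_names(trait, coords = !is.null(coords))
  keep_names <- intersect(keep_names, colnames(W))
  W <- W[, keep_names, drop = FALSE]
  if (is.null(train_index)) train_index <- seq_len(nrow(W))
  ctr <- colMeans(W[train_index, , drop = FALSE])
  scl <- apply(W[train_index, , drop = FALSE], 2, stats::sd)
  zv <- !is.finite(scl) | scl < 1e-12
  if (any(zv)) {
    warning("dropping zero-variance EC column(s): ",
            paste(colnames(W)[zv], collapse = ", "))
    W <- W[, !zv, drop = FALSE]; ctr <- ctr[!zv]; scl <- scl[!zv]
  }
  if (standardize) W <- sweep(sweep(W, 2, ctr), 2, scl, "/")
  attr(W, "center") <- ctr
  attr(W, "scale") <- scl
  attr(W, "trait") <- trait
  class(W) <- c("ec_matrix", class(W))
  W
}

#' Principal component analysis of per-environment weather covariates
#'
#' PCA of the environment x weather-covariate table, one row per environment
#' with growth windows anchored at the environment's median silking date.
#' Used to examine clustering of environments by climatic similarity.
#'
#' @param W_env numeric matrix, one row per environment (>= 3), columns =
#'   weather covariates.
#' @return list with `scores`, `loadings` and `variance_fraction` (sums to 1).
#' @export
environment_pca <- function(W_env) {
  W_env <- as.matrix(W_env)
  if (nrow(W_env) < 3) stop("environment PCA needs at least 3 environments")
  scl <- apply(W_env, 2, stats::sd)
  W_env <- W_env[, scl > 1e-12, drop = FALSE]
  p <- stats::prcomp(W_env, center = TRUE, scale. = TRUE)
  list(scores = p$x, loadings = p$rotation,
       variance_fraction = p$sdev^2 / sum(p$sdev^2))
}
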