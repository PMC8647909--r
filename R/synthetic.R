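#' Configuration for the synthetic multi-environment-trial generator
#'
#' Defaults describe a desk-scale maize MET: a hybrid panel derived from a
#' modest inbred set, evaluated in a site-by-year trial network with two
#' replicates, with a grain-yield-like trait (Mg/ha) whose
#' genotype-by-environment components are of the same order as the additive
#' genetic component.
#'
#' @param n_inbreds,n_markers,n_sites,n_years,n_hybrids,n_reps dimensions of
#'   the simulated network.
#' @param prop_tested fraction of hybrids evaluated in each environment
#'   (unbalancedness of the network).
#' @param variance_components named list of nonnegative generative variances:
#'   `sigma2_E` (environment deviation), `sigma2_S` (site), `sigma2_Y`
#'   (year), `sigma2_g` (additive genomic), `sigma2_w` (environmental
#'   covariate main effects), `sigma2_gw` (marker-by-covariate interaction),
#'   `sigma2_gE` (genotype-by-environment), `sigma2_rep` (replicate),
#'   `sigma2_resid` (plot residual).
#' @param mu general mean in trait units.
#' @param missing_rate,het_rate fractions in `[0, 1]` of missing and
#'   heterozygous calls injected into the inbred marker matrix.
#' @param multiallelic_rate fraction of markers tagged as having a third
#'   observed allele (to exercise the biallelic filter).
#' @param maf_target mean minor allele frequency of simulated markers.
#' @param fault_rates list of per-day weather-fault probabilities: `stuck`
#'   (a sensor repeats one value all day), `gap` (most records of the day
#'   missing), `spike` (one out-of-range record).
#' @param n_outliers number of plots shifted by `outlier_k` residual SDs.
#' @param outlier_k outlier shift in residual standard deviations.
#' @param req_mean,req_sd mean and SD of the per-hybrid thermal requirement
#'   (growing degree days base 10 from planting to 50 percent silking).
#' @param w_active_frac fraction of EC columns carrying the EC main effect
#'   (1 = dense IID draws, the random-regression assumption of the
#'   reaction-norm model).
#' @param gw_active_frac fraction of EC columns interacting with the
#'   genome.
#' @param gw_pc_align align the interacting marker coefficients with the
#'   leading axes of genetic variation (`FALSE` = dense IID coefficients,
#'   giving exactly the Hadamard covariance the reaction-norm model
#'   assumes).
#' @param effects_from_kernels draw every random term exactly from its
#'   model covariance (`N(0, sigma2_k K_k)` with the same kernels the
#'   reaction-norm model uses) instead of from marker/covariate-level
#'   effects. Under this mode the configured variances are the true kernel
#'   parameters, which is what parameter-recovery studies require.
#' @param seed integer seed; all downstream randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_inbreds = 50, n_markers = 800, n_sites = 5,
                       n_years = 4, n_hybrids = 120, n_reps = 2,
                       prop_tested = 0.65,
                       variance_components = list(
                         sigma2_E = 1.0, sigma2_S = 0.4, sigma2_Y = 0.3,
                         sigma2_g = 0.4, sigma2_w = 0.35, sigma2_gw = 0.3,
                         sigma2_gE = 0.3, sigma2_rep = 0.05,
                         sigma2_resid = 0.7),
                       mu = 7, missing_rate = 0.05, het_rate = 0.02,
                       multiallelic_rate = 0.03, maf_target = 0.3,
                       fault_rates = list(stuck = 0, gap = 0, spike = 0),
                       n_outliers = 0, outlier_k = 6,
                       req_mean = 750, req_sd = 40,
                       w_active_frac = 0.25, gw_active_frac = 0.3,
                       gw_pc_align = TRUE, effects_from_kernels = FALSE,
                       seed = 1L) {
  vc0 <- list(sigma2_E = 0, sigma2_S = 0, sigma2_Y = 0, sigma2_g = 0,
              sigma2_w = 0, sigma2_gw = 0, sigma2_gE = 0, sigma2_rep = 0,
              sigma2_resid = 0)
  vc0[names(variance_components)] <- variance_components
  if (any(unlist(vc0) < 0)) stop("variance components must be nonnegative")
  stopifnot(n_reps >= 1,
            missing_rate >= 0, missing_rate <= 1,
            het_rate >= 0, het_rate <= 1,
            prop_tested > 0, prop_tested <= 1)
  structure(list(
    n_inbreds = n_inbreds, n_markers = n_markers, n_sites = n_sites,
    n_years = n_years, n_hybrids = n_hybrids, n_reps = n_reps,
    prop_tested = prop_tested, variance_components = vc0, mu = mu,
    missing_rate = missing_rate, het_rate = het_rate,
    multiallelic_rate = multiallelic_rate, maf_target = maf_target,
    fault_rates = fault_rates, n_outliers = n_outliers,
    outlier_k = outlier_k, req_mean = req_mean, req_sd = req_sd,
    w_active_frac = w_active_frac, gw_active_frac = gw_active_frac,
    gw_pc_align = gw_pc_align,
    effects_from_kernels = effects_from_kernels,
    seed = as.integer(seed)), class = "sim_config")
}

derive_seed <- function(seed, ...) {
  off <- c(...)
  as.integer((as.numeric(seed) * 7919 + sum(off * 101^(seq_along(off) - 1))) %%
               2147483647)
}

#' Simulate inbred marker genotypes
#'
#' Markers come in linkage blocks of about 20 loci: each block has eight
#' founder haplotypes drawn at per-marker allele frequencies averaging
#' `maf_target`, and every inbred copies one founder per block with a small
#' mutation rate, giving strong within-block LD (including duplicated
#' columns) so pruning has work to do. Inbreds are fully homozygous (dosages
#' 0/2) apart from an injected fraction `het_rate` of heterozygous calls and
#' `missing_rate` of missing calls. A `clean` attribute holds the matrix
#' before injection (generative truth) and an `allele_counts` attribute tags
#' a fraction of markers as multi-allelic for the biallelic filter.
#'
#' @param cfg a [sim_config()].
#' @return marker matrix (inbreds x markers) with attributes `clean`,
#'   `allele_counts`, `map`.
#' @export
simulate_inbred_genotypes <- function(cfg) {
  if (cfg$n_inbreds < 2 || cfg$n_markers < 1)
    stop("need at least 2 inbreds and 1 marker")
  set.seed(derive_seed(cfg$seed, 11))
  n <- cfg$n_inbreds; p <- cfg$n_markers
  block <- 20L
  n_blocks <- ceiling(p / block)
  half <- min(cfg$maf_target, 0.5)
  # founder frequencies sit slightly above the target to offset the
  # folding loss (min(f, 1-f)) from founder sampling and mutation
  lo <- max(half - 0.15, 0.02); hi <- min(half + 0.2, 0.55)
  freq <- stats::runif(p, lo, hi)
  n_founders <- 8L
  hap <- matrix(0L, n, p)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1) * block + 1):min(b * block, p)
    founders <- matrix(stats::rbinom(n_founders * length(cols), 1,
                                     rep(freq[cols], each = n_founders)),
                       nrow = n_founders)
    pick <- sample.int(n_founders, n, replace = TRUE)
    hb <- founders[pick, , drop = FALSE]
    mut <- matrix(stats::runif(n * length(cols)) < 0.05, n)
    hb[mut] <- 1L - hb[mut]
    hap[, cols] <- hb
  }
  m <- 2L * hap
  rownames(m) <- sprintf("I%03d", seq_len(n))
  colnames(m) <- sprintf("M%05d", seq_len(p))
  clean <- m
  if (cfg$het_rate > 0) {
    hz <- matrix(stats::runif(n * p) < cfg$het_rate, n)
    m[hz] <- 1L
  }
  if (cfg$missing_rate > 0) {
    ms <- matrix(stats::runif(n * p) < cfg$missing_rate, n)
    m[ms] <- NA_integer_
  }
  ac <- rep(2L, p)
  nma <- round(cfg$multiallelic_rate * p)
  if (nma > 0) ac[sample.int(p, nma)] <- 3L
  attr(m, "clean") <- clean
  attr(m, "allele_counts") <- ac
  attr(m, "map") <- data.frame(marker = colnames(m),
                               chrom = rep(1L, p), pos = seq_len(p))
  m
}

#' Plan in-silico hybrid crosses
#'
#' Samples unique unordered parent pairs (no selfs) from the inbred panel.
#'
#' @param inbreds inbred marker matrix (row names are parent ids).
#' @param n_hybrids number of crosses; at most `choose(n_inbreds, 2)`.
#' @param seed integer seed.
#' @return data.frame `hybrid`, `parent1`, `parent2`.
#' @export
plan_hybrids <- function(inbreds, n_hybrids, seed = 1L) {
  ids <- rownames(inbreds)
  n <- length(ids)
  total <- n * (n - 1) / 2
  if (n_hybrids > total)
    stop(sprintf("requested %d hybrids but only %d crosses possible",
                 n_hybrids, total))
  set.seed(derive_seed(seed, 13))
  all_pairs <- utils::combn(n, 2)
  pick <- sort(sample.int(ncol(all_pairs), n_hybrids))
  data.frame(hybrid = sprintf("H%04d", seq_len(n_hybrids)),
             parent1 = ids[all_pairs[1, pick]],
             parent2 = ids[all_pairs[2, pick]],
             stringsAsFactors = FALSE)
}

#' Climate parameters for a synthetic trial site
#'
#' @param site site id.
#' @param latitude,longitude,elevation site geography.
#' @param t_mid annual mean temperature (degrees C).
#' @param t_amp seasonal amplitude of the daily mean temperature.
#' @param dtr mean diurnal temperature range.
#' @param rain_p01,rain_p11 Markov chain transition probabilities
#'   dry-to-wet and wet-to-wet.
#' @param rain_shape,rain_scale gamma parameters of daily wet-day amounts.
#' @param rh_base mean relative humidity (percent).
#' @param wind_base mean wind speed (m/s).
#' @return list of class `climate_params`.
#' @export
climate_params <- function(site, latitude = 40, longitude = -90,
                           elevation = 250, t_mid = 11, t_amp = 13,
                           dtr = 10, rain_p01 = 0.25, rain_p11 = 0.5,
                           rain_shape = 0.8, rain_scale = 9,
                           rh_base = 70, wind_base = 2.5) {
  structure(list(site = site, latitude = latitude, longitude = longitude,
                 elevation = elevation, t_mid = t_mid, t_amp = t_amp,
                 dtr = dtr, rain_p01 = rain_p01, rain_p11 = rain_p11,
                 rain_shape = rain_shape, rain_scale = rain_scale,
                 rh_base = rh_base, wind_base = wind_base),
            class = "climate_params")
}

# Daily weather core: sinusoidal seasonal cycle + AR(1) anomalies for
# temperature, two-state Markov rainfall with gamma amounts, bounded noise
# around seasonal means for humidity, wind and solar radiation.
simulate_daily_series <- function(site_params, year, seed,
                                  season_start = "-04-10",
                                  season_days = 210L) {
  sp <- site_params
  set.seed(derive_seed(seed, 17, year))
  start <- as.Date(paste0(year, season_start))
  dates <- seq(start, by = "day", length.out = season_days)
  doy <- as.integer(strftime(dates, "%j"))
  tmean_clim <- sp$t_mid + sp$t_amp * cos(2 * pi * (doy - 200) / 365)
  ar <- stats::filter(stats::rnorm(season_days, 0, 1.8), 0.7,
                      method = "recursive")
  tmean <- tmean_clim + as.numeric(ar)
  wet <- logical(season_days); wet[1] <- stats::runif(1) < 0.3
  for (i in 2:season_days)
    wet[i] <- stats::runif(1) < if (wet[i - 1]) sp$rain_p11 else sp$rain_p01
  prcp <- ifelse(wet, stats::rgamma(season_days, sp$rain_shape,
                                    scale = sp$rain_scale), 0)
  # cloud cover on wet days compresses the diurnal range
  half_dtr <- sp$dtr / 2 * stats::runif(season_days, 0.8, 1.2) *
    ifelse(wet, 0.75, 1)
  tmax <- tmean + half_dtr
  tmin <- tmean - half_dtr
  daylen <- day_length(sp$latitude, doy)
  srad_clear <- pmax(30 * sin(pi * pmin(daylen, 24) / 24)^1.5, 5)
  cloud <- ifelse(wet, stats::runif(season_days, 0.4, 0.8),
                  stats::runif(season_days, 0.05, 0.35))
  srad <- srad_clear * (1 - 0.75 * cloud)
  rh <- pmin(pmax(sp$rh_base + ifelse(wet, 10, 0) +
                    stats::rnorm(season_days, 0, 6), 25), 100)
  wind <- pmin(pmax(stats::rnorm(season_days, sp$wind_base, 0.8), 0.2), 15)
  data.frame(site = sp$site, year = year, date = dates,
             tmax = tmax, tmin = tmin, tmean = (tmax + tmin) / 2,
             prcp = prcp, rh = rh, srad = srad, wind = wind,
             irrigation = 0,
             flag_count = FALSE, flag_range = FALSE,
             flag_persistence = FALSE, flag_consistency = FALSE,
             flag_imputed = FALSE, stringsAsFactors = FALSE)
}

#' Simulate sub-daily weather-station records
#'
#' Expands a daily weather realization to a nominal 48 records per day
#' (30-minute cadence): temperature follows a diurnal sine with the maximum
#' at 14:00, solar radiation a half-sine over the daylight hours scaled to
#' the daily energy, rainfall is split over a few wet records, and humidity
#' and wind vary smoothly around their daily means. Sensor faults are
#' injected at the configured daily rates: `stuck` (one variable repeats its
#' first value all day, zero variance), `gap` (a random 60 percent of the
#' day's records dropped), `spike` (one physically impossible temperature).
#'
#' @param site_params a [climate_params()].
#' @param year calendar year of the season.
#' @param seed integer seed.
#' @param season_start month-day suffix of the season start (default
#'   April 10).
#' @param season_days season length in days (>= 120).
#' @param fault_rates list with elements `stuck`, `gap`, `spike`.
#' @return long data.frame `site`, `timestamp`, `variable`, `value`.
#' @export
simulate_daily_weather <- function(site_params, year, seed,
                                   season_start = "-04-10",
                                   season_days = 210L,
                                   fault_rates = list(stuck = 0, gap = 0,
                                                      spike = 0)) {
  if (season_days < 120) stop("season length must be at least 120 days")
  daily <- simulate_daily_series(site_params, year, seed, season_start,
                                 season_days)
  set.seed(derive_seed(seed, 19, year))
  hrs <- seq(0, 23.5, by = 0.5)
  doy <- as.integer(strftime(daily$date, "%j"))
  recs <- vector("list", nrow(daily))
  for (i in seq_len(nrow(daily))) {
    mid <- (daily$tmax[i] + daily$tmin[i]) / 2
    amp <- (daily$tmax[i] - daily$tmin[i]) / 2
    temp <- mid + amp * cos(2 * pi * (hrs - 14) / 24)
    daylen <- day_length(site_params$latitude, doy[i])
    sunrise <- 12 - daylen / 2
    frac <- (hrs - sunrise) / daylen
    srad_w <- ifelse(frac > 0 & frac < 1,
                     pi / 2 * daily$srad[i] * 1e6 / (daylen * 3600) *
                       sin(pi * frac), 0)
    rain <- numeric(48)
    if (daily$prcp[i] > 0) {
      k <- sample(3:8, 1)
      slots <- sample.int(48, k)
      w <- stats::rgamma(k, 1); w <- w / sum(w)
      rain[slots] <- daily$prcp[i] * w
    }
    rh <- pmin(pmax(daily$rh[i] - 10 * cos(2 * pi * (hrs - 4) / 24) +
                      stats::rnorm(48, 0, 1.5), 5), 100)
    wind <- pmax(daily$wind[i] + stats::rnorm(48, 0, 0.4), 0)
    # fault injection
    keep <- rep(TRUE, 48)
    if (stats::runif(1) < fault_rates$gap) keep[sample.int(48, 29)] <- FALSE
    for (v in c("temperature", "rh", "wind", "srad")) {
      if (stats::runif(1) < fault_rates$stuck) {
        if (v == "temperature") temp[] <- temp[1]
        if (v == "rh") rh[] <- rh[1]
        if (v == "wind") wind[] <- wind[1]
        if (v == "srad") srad_w[] <- srad_w[1]
      }
    }
    if (stats::runif(1) < fault_rates$spike) temp[sample.int(48, 1)] <- 75
    ts <- as.POSIXct(paste(daily$date[i], "00:00:00"), tz = "UTC") +
      hrs * 3600
    recs[[i]] <- data.frame(
      site = site_params$site,
      timestamp = rep(ts[keep], 5),
      variable = rep(c("temperature", "rh", "rainfall", "srad", "wind"),
                     each = sum(keep)),
      value = c(temp[keep], rh[keep], rain[keep], srad_w[keep], wind[keep]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Simulate a soil profile for a site
#'
#' Sand, silt and clay fractions are a normalized gamma draw summing to 100
#' percent; organic matter is uniform within configurable bounds.
#'
#' @param site site id.
#' @param seed integer seed.
#' @param om_bounds organic matter bounds (percent), within `[0, 15]`.
#' @return one-row data.frame `site`, `SandProp.SC`, `Silt.Prop.SC`,
#'   `ClayProp.SC`, `OM.SC`.
#' @export
simulate_soil <- function(site, seed = 1L, om_bounds = c(0.5, 8)) {
  set.seed(derive_seed(seed, 23, nchar(site) + sum(utf8ToInt(site))))
  g <- stats::rgamma(3, shape = c(4, 3.5, 2.5), scale = 1)
  comp <- 100 * g / sum(g)
  data.frame(site = site, SandProp.SC = comp[1], Silt.Prop.SC = comp[2],
             ClayProp.SC = comp[3],
             OM.SC = stats::runif(1, om_bounds[1], om_bounds[2]),
             stringsAsFactors = FALSE)
}

#' Silking date from a thermal-time requirement
#'
#' The 50 percent silking date is the first day, counting from the day after
#' planting, on which the cumulative daily growing degrees (base 10) since
#' planting reach the hybrid's thermal requirement.
#'
#' @param hybrid hybrid id (must index
#'   `truth$silking_thermal_requirement`).
#' @param weather daily weather series covering the season.
#' @param planting planting `Date`.
#' @param truth truth record with `silking_thermal_requirement` (named) and
#'   `gdd_base`.
#' @return silking `Date`, strictly after planting.
#' @export
simulate_phenology <- function(hybrid, weather, planting, truth) {
  req <- truth$silking_thermal_requirement[[hybrid]]
  if (is.null(req) || is.na(req)) stop("unknown hybrid: ", hybrid)
  base <- if (!is.null(truth$gdd_base)) truth$gdd_base else 10
  days <- weather$date > planting
  d <- weather[days, , drop = FALSE]
  d <- d[order(d$date), , drop = FALSE]
  gdd <- cumsum(daily_growing_degrees(d$tmin, d$tmax, base))
  hit <- which(gdd >= req)
  if (!length(hit))
    stop("season too short: thermal requirement ", req,
         " never reached for hybrid ", hybrid)
  d$date[hit[1]]
}

scale_to_var <- function(x, s2) {
  if (s2 <= 0) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(s2) / s
}

#' Simulate plot phenotypes from the generative variance-component model
#'
#' Plot values are built as mean + environment (site + year + environment
#' deviation) + genomic value (a linear combination of the markers) +
#' environmental-covariate main effect (random regression on W) +
#' marker-by-covariate interaction (sparse marker-interaction coefficients
#' per EC) + genotype-by-environment deviation (independent genomic vectors
#' per environment) + replicate effect + residual. Each realized term is
#' rescaled so its sample variance equals the configured component exactly,
#' and the realized values are recorded in the returned truth record.
#'
#' @param cfg a [sim_config()].
#' @param genotypes hybrid dosage matrix (true, complete).
#' @param W standardized EC matrix with row names `environment:hybrid`.
#' @param design plot design data.frame: `environment`, `site`, `year`,
#'   `hybrid`, `replicate`, `planting_date`, `silking_date`.
#' @return list with `plots` (design + `trait`, plus `outlier` flag) and
#'   `truth` (marker effects, realized components, per-term values).
#' @export
simulate_phenotypes <- function(cfg, genotypes, W, design) {
  vc <- cfg$variance_components
  set.seed(derive_seed(cfg$seed, 29))
  obs_id <- paste(design$environment, design$hybrid, sep = ":")
  uobs <- !duplicated(obs_id)
  obs <- design[uobs, c("environment", "site", "year", "hybrid")]
  oid <- obs_id[uobs]
  if (!setequal(rownames(W), oid) || nrow(W) != length(oid))
    stop("misaligned W: rows must be the environment:hybrid observations")
  Wm <- as.matrix(W)[oid, , drop = FALSE]
  n_obs <- nrow(obs)
  X <- genotypes[obs$hybrid, , drop = FALSE]
  Xc <- scale(genotypes, center = TRUE, scale = FALSE)

  envs <- unique(obs$environment)
  sites <- unique(obs$site); years <- unique(obs$year)
  kernel_mode <- isTRUE(cfg$effects_from_kernels)

  if (kernel_mode) {
    # draw each term exactly from its model covariance: the configured
    # variances are then the true kernel parameters of the reaction-norm
    # model rather than targets for post-hoc rescaling
    G <- compute_grm(genotypes)
    cG <- chol(G + diag(1e-8, nrow(G)))
    draw_G <- function(s2) {
      a <- sqrt(s2) * as.numeric(crossprod(cG, stats::rnorm(nrow(G))))
      names(a) <- rownames(genotypes)
      a
    }
    e_env <- stats::rnorm(length(envs), 0, sqrt(vc$sigma2_E))
    names(e_env) <- envs
    e_site <- stats::rnorm(length(sites), 0, sqrt(vc$sigma2_S))
    names(e_site) <- sites
    e_year <- stats::rnorm(length(years), 0, sqrt(vc$sigma2_Y))
    names(e_year) <- as.character(years)
    term_E <- unname(e_env[obs$environment])
    term_S <- unname(e_site[obs$site])
    term_Y <- unname(e_year[as.character(obs$year)])
    g_draw <- draw_G(vc$sigma2_g)
    term_g <- unname(g_draw[obs$hybrid])
    b_scaled <- rep(0, ncol(genotypes))
    q <- ncol(Wm)
    gamma <- stats::rnorm(q, 0, sqrt(vc$sigma2_w / q))
    term_w <- as.numeric(Wm %*% gamma)
    # gw ~ N(0, s2 * [WW'/q] o K_G): independent genomic vectors per EC
    term_gw <- rep(0, n_obs)
    if (vc$sigma2_gw > 0) {
      A <- vapply(seq_len(q), function(k)
        draw_G(vc$sigma2_gw / q)[obs$hybrid], numeric(n_obs))
      term_gw <- rowSums(Wm * A)
    }
    term_gE <- rep(0, n_obs)
    if (vc$sigma2_gE > 0) {
      for (e in envs) {
        a <- draw_G(vc$sigma2_gE)
        sel <- obs$environment == e
        term_gE[sel] <- a[obs$hybrid[sel]]
      }
    }
    obs_lin <- cfg$mu + term_E + term_S + term_Y + term_g + term_w +
      term_gw + term_gE
    names(obs_lin) <- oid
    rep_id <- paste(design$environment, design$replicate, sep = ":")
    ureps <- unique(rep_id)
    r_eff <- stats::rnorm(length(ureps), 0, sqrt(vc$sigma2_rep))
    names(r_eff) <- ureps
    term_rep <- unname(r_eff[rep_id])
    term_res <- stats::rnorm(nrow(design), 0, sqrt(vc$sigma2_resid))
    trait <- obs_lin[obs_id] + term_rep + term_res
    plots <- design
    plots$trait <- as.numeric(trait)
    plots$outlier <- FALSE
    truth <- list(
      marker_effects = b_scaled,
      true_components = unlist(vc[c("sigma2_E", "sigma2_S", "sigma2_Y",
                                    "sigma2_g", "sigma2_w", "sigma2_gw",
                                    "sigma2_gE", "sigma2_rep",
                                    "sigma2_resid")]),
      realized_variances = vapply(
        list(E = term_E, S = term_S, Y = term_Y, g = term_g, w = term_w,
             gw = term_gw, gE = term_gE, rep = term_rep, resid = term_res),
        stats::var, numeric(1)),
      environment_effects = e_env,
      obs_linear_predictor = obs_lin,
      terms = data.frame(obs = oid, E = term_E, S = term_S, Y = term_Y,
                         g = term_g, w = term_w, gw = term_gw,
                         gE = term_gE))
    names(truth$true_components) <- c("E", "S", "Y", "g", "w", "gw", "gE",
                                      "rep", "resid")
    return(list(plots = plots, truth = truth))
  }

  e_env <- stats::rnorm(length(envs)); names(e_env) <- envs
  e_site <- stats::rnorm(length(sites)); names(e_site) <- sites
  e_year <- stats::rnorm(length(years)); names(e_year) <- as.character(years)
  term_E <- scale_to_var(e_env[obs$environment], vc$sigma2_E)
  term_S <- scale_to_var(e_site[obs$site], vc$sigma2_S)
  term_Y <- scale_to_var(e_year[as.character(obs$year)], vc$sigma2_Y)

  b <- stats::rnorm(ncol(genotypes))
  g_hyb <- as.numeric(Xc %*% b); names(g_hyb) <- rownames(genotypes)
  term_g <- scale_to_var(g_hyb[obs$hybrid], vc$sigma2_g)
  b_scaled <- if (vc$sigma2_g > 0 && stats::sd(g_hyb[obs$hybrid]) > 1e-12)
    b * sqrt(vc$sigma2_g) / stats::sd(g_hyb[obs$hybrid]) else b * 0

  # by default a few environmental drivers dominate (heat around
  # flowering, water, soil organic matter in real maize panels): the EC
  # main effect loads on a sparse subset of covariates. With
  # w_active_frac = 1 the draws are dense IID, matching the random
  # regression assumption of the reaction-norm model exactly.
  q <- ncol(Wm)
  gamma <- numeric(q)
  n_act <- max(2L, round((cfg$w_active_frac %||% 0.25) * q))
  n_act <- min(n_act, q)
  act_w <- sample.int(q, n_act)
  gamma[act_w] <- stats::rnorm(n_act)
  term_w <- scale_to_var(as.numeric(Wm %*% gamma), vc$sigma2_w)

  # gw: sum_q W_q * (x . c_q). By default only a sparse subset of ECs
  # interacts with the genome and the interacting marker combinations c_q
  # load on the leading axes of genetic variation (in maize,
  # genotype-by-environment response is driven to a large extent by
  # adaptation loci - e.g. flowering time - that co-vary with population
  # structure), plus a sparse marker-specific part. With
  # gw_active_frac = 1 and gw_pc_align = FALSE the coefficients are dense
  # IID draws, whose covariance is exactly the Hadamard structure
  # G o Omega assumed by the reaction-norm model.
  act_frac <- cfg$gw_active_frac %||% 0.3
  align <- isTRUE(cfg$gw_pc_align %||% TRUE)
  act_gw <- sample.int(q, min(q, max(2L, round(act_frac * q))))
  Cmat <- matrix(0, ncol(genotypes), q)
  if (align) {
    n_axes <- min(5L, nrow(genotypes) - 1L, ncol(genotypes))
    pc_load <- stats::prcomp(Xc, center = FALSE, rank. = n_axes)$rotation
    nz <- max(1L, round(0.1 * ncol(genotypes)))
    for (k in act_gw) {
      Cmat[, k] <- pc_load %*% stats::rnorm(n_axes)
      idx <- sample.int(ncol(genotypes), nz)
      Cmat[idx, k] <- Cmat[idx, k] + stats::rnorm(nz, 0, 0.2)
    }
  } else {
    for (k in act_gw)
      Cmat[, k] <- stats::rnorm(ncol(genotypes))
  }
  XC <- Xc[obs$hybrid, , drop = FALSE] %*% Cmat
  term_gw <- scale_to_var(rowSums(Wm * XC), vc$sigma2_gw)

  # gE: per environment an independent genomic vector a_i ~ N(0, G)
  term_gE <- rep(0, n_obs)
  if (vc$sigma2_gE > 0) {
    G <- compute_grm(genotypes)
    cG <- chol(G + diag(1e-6, nrow(G)))
    raw <- numeric(n_obs)
    for (e in envs) {
      a <- as.numeric(crossprod(cG, stats::rnorm(nrow(G))))
      names(a) <- rownames(genotypes)
      sel <- obs$environment == e
      raw[sel] <- a[obs$hybrid[sel]]
    }
    term_gE <- scale_to_var(raw, vc$sigma2_gE)
  }

  obs_lin <- cfg$mu + term_E + term_S + term_Y + term_g + term_w + term_gw +
    term_gE
  names(obs_lin) <- oid

  rep_id <- paste(design$environment, design$replicate, sep = ":")
  ureps <- unique(rep_id)
  r_eff <- stats::rnorm(length(ureps)); names(r_eff) <- ureps
  term_rep <- scale_to_var(r_eff[rep_id], vc$sigma2_rep)
  term_res <- scale_to_var(stats::rnorm(nrow(design)), vc$sigma2_resid)

  trait <- obs_lin[obs_id] + term_rep + term_res
  plots <- design
  plots$trait <- as.numeric(trait)
  plots$outlier <- FALSE
  if (cfg$n_outliers > 0) {
    sd_res <- sqrt(max(vc$sigma2_resid, 1e-8))
    hit <- sample.int(nrow(plots), min(cfg$n_outliers, nrow(plots)))
    plots$trait[hit] <- plots$trait[hit] +
      cfg$outlier_k * sd_res * sign(stats::rnorm(length(hit)))
    plots$outlier[hit] <- TRUE
  }
  truth <- list(
    marker_effects = b_scaled,
    true_components = vapply(
      list(E = term_E, S = term_S, Y = term_Y, g = term_g, w = term_w,
           gw = term_gw, gE = term_gE, rep = term_rep, resid = term_res),
      stats::var, numeric(1)),
    environment_effects = tapply(term_E, obs$environment, mean),
    obs_linear_predictor = obs_lin,
    terms = data.frame(obs = oid, E = term_E, S = term_S, Y = term_Y,
                       g = term_g, w = term_w, gw = term_gw, gE = term_gE))
  list(plots = plots, truth = truth)
}

#' Generate a complete synthetic MET dataset
#'
#' Runs the whole generator: inbred genotypes, hybrid pedigree and true
#' hybrid dosages, site geography/climate/soil, daily weather per site and
#' year, per-hybrid silking dates from thermal time, the standardized EC
#' matrix, and plot phenotypes from the variance-component model.
#'
#' @param cfg a [sim_config()].
#' @param trait trait id controlling the EC column mask.
#' @param coords include longitude/latitude in W (default `TRUE`).
#' @return list with elements `cfg`, `inbreds`, `pedigree`, `hybrids` (true
#'   dosages), `sites`, `soil`, `weather` (named list of derived daily
#'   series per site:year), `obs` (hybrid-by-environment table), `W`,
#'   `plots`, `truth`.
#' @export
simulate_met <- function(cfg = sim_config(), trait = "grain_yield",
                         coords = TRUE) {
  inbreds <- simulate_inbred_genotypes(cfg)
  pedigree <- plan_hybrids(inbreds, cfg$n_hybrids, cfg$seed)
  clean <- attr(inbreds, "clean")
  hybrids <- (clean[pedigree$parent1, , drop = FALSE] +
                clean[pedigree$parent2, , drop = FALSE]) / 2
  rownames(hybrids) <- pedigree$hybrid

  set.seed(derive_seed(cfg$seed, 31))
  lat <- seq(34, 45, length.out = cfg$n_sites) +
    stats::runif(cfg$n_sites, -1, 1)
  lon <- stats::runif(cfg$n_sites, -100, -80)
  elev <- stats::runif(cfg$n_sites, 100, 400)
  sites <- data.frame(site = sprintf("S%02d", seq_len(cfg$n_sites)),
                      latitude = lat, longitude = lon, elevation = elev,
                      stringsAsFactors = FALSE)
  years <- 2014:(2013 + cfg$n_years)
  dtr_site <- stats::runif(cfg$n_sites, 8.5, 13.5)
  params <- lapply(seq_len(cfg$n_sites), function(i)
    climate_params(sites$site[i], latitude = lat[i], longitude = lon[i],
                   elevation = elev[i],
                   t_mid = 18 - 0.45 * (lat[i] - 34),
                   t_amp = 11 + 0.2 * (lat[i] - 34),
                   dtr = dtr_site[i]))
  soil <- do.call(rbind, lapply(sites$site, simulate_soil, seed = cfg$seed))

  weather <- list()
  planting <- list()
  for (i in seq_len(cfg$n_sites)) for (y in years) {
    key <- paste(sites$site[i], y, sep = ":")
    d <- simulate_daily_series(params[[i]], y, cfg$seed)
    weather[[key]] <- derive_daily(d, lat[i], elev[i])
    set.seed(derive_seed(cfg$seed, 37, i, y))
    planting[[key]] <- d$date[1] + sample(5:20, 1)
  }

  set.seed(derive_seed(cfg$seed, 41))
  req <- stats::rnorm(cfg$n_hybrids, cfg$req_mean, cfg$req_sd)
  names(req) <- pedigree$hybrid
  truth0 <- list(silking_thermal_requirement = req, gdd_base = 10)

  # yearly cohorts: every hybrid enters in some year and stays for one to
  # three seasons, as in a real trial network where new material enters and
  # older material is dropped -- this is what makes leave-one-year-out
  # prediction of untested genotypes (CV00) a nonempty problem
  set.seed(derive_seed(cfg$seed, 42))
  entry <- sample(years, cfg$n_hybrids, replace = TRUE)
  stay <- sample(1:3, cfg$n_hybrids, replace = TRUE)
  active <- lapply(years, function(y)
    which(entry <= y & y < entry + stay))
  names(active) <- as.character(years)
  # guarantee at least a handful of hybrids per year
  for (y in as.character(years))
    if (length(active[[y]]) < 5)
      active[[y]] <- sort(union(active[[y]],
                                sample.int(cfg$n_hybrids, 5)))

  obs <- NULL
  for (i in seq_len(cfg$n_sites)) for (y in years) {
    key <- paste(sites$site[i], y, sep = ":")
    set.seed(derive_seed(cfg$seed, 43, i, y))
    pool <- active[[as.character(y)]]
    tested <- sort(sample(pool,
                          max(2L, round(cfg$prop_tested * length(pool)))))
    env <- paste0(y, "_", sites$site[i])
    w <- weather[[key]]
    pl <- planting[[key]]
    # silking depends on the hybrid only through its thermal requirement:
    # compute the date per unique requirement via the cumulative GDD curve
    after <- w[w$date > pl, , drop = FALSE]
    cumgdd <- cumsum(after$gdd)
    silk_of <- function(r) {
      h <- which(cumgdd >= r)
      if (!length(h)) stop("season too short in ", key)
      after$date[h[1]]
    }
    silks <- as.Date(vapply(req[tested], function(r)
      as.character(silk_of(r)), character(1)))
    obs <- rbind(obs, data.frame(
      environment = env, site = sites$site[i], year = y,
      hybrid = pedigree$hybrid[tested], planting_date = pl,
      silking_date = silks, stringsAsFactors = FALSE))
  }

  # stage covariates per observation (cached per environment x silking date)
  sc_cache <- new.env(parent = emptyenv())
  covs <- matrix(NA_real_, nrow(obs), 39)
  for (r in seq_len(nrow(obs))) {
    key <- paste(obs$site[r], obs$year[r], sep = ":")
    ck <- paste(key, obs$silking_date[r])
    val <- sc_cache[[ck]]
    if (is.null(val)) {
      wn <- stage_windows(obs$planting_date[r], obs$silking_date[r])
      val <- stage_covariates(weather[[key]], wn)
      sc_cache[[ck]] <- val
    }
    covs[r, ] <- val
  }
  colnames(covs) <- names(sc_cache[[ls(sc_cache)[1]]])
  rownames(covs) <- paste(obs$environment, obs$hybrid, sep = ":")
  coord_df <- if (coords) {
    j <- match(obs$site, sites$site)
    data.frame(longitude = sites$longitude[j], latitude = sites$latitude[j])
  } else NULL
  W <- assemble_W(covs, soil, obs$site, coords = coord_df, trait = trait)

  design <- obs[rep(seq_len(nrow(obs)), each = cfg$n_reps), , drop = FALSE]
  design$replicate <- rep(seq_len(cfg$n_reps), nrow(obs))
  rownames(design) <- NULL
  sim <- simulate_phenotypes(cfg, hybrids, W, design)
  truth <- c(truth0, sim$truth)
  list(cfg = cfg, inbreds = inbreds, pedigree = pedigree, hybrids = hybrids,
       sites = sites, soil = soil, weather = weather, obs = obs, W = W,
       plots = sim$plots, truth = truth)
}
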