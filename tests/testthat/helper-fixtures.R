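# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# small complete MET simulation used by several files
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_inbreds = 20, n_markers = 200, n_sites = 3,
                      n_years = 2, n_hybrids = 30, seed = 7)
    .fixture_env$sim <- suppressWarnings(simulate_met(cfg))
  }
  .fixture_env$sim
}

# a derived daily series with constant weather, handy for EC window tests
constant_daily <- function(dates, tmin = 15, tmax = 25, prcp = 0, rh = 60,
                           srad = 20, wind = 2, et0 = 4) {
  n <- length(dates)
  d <- data.frame(date = dates, tmax = tmax, tmin = tmin,
                  tmean = (tmin + tmax) / 2, prcp = prcp, rh = rh,
                  srad = srad, wind = wind, irrigation = 0)
  d$water_in <- d$prcp
  d$gdd <- daily_growing_degrees(d$tmin, d$tmax, 10)
  d$daylen <- 14
  d$ptt <- d$gdd * d$daylen
  d$vpd <- vapor_pressure_deficit(d$tmin, d$tmax, d$rh)
  d$et0 <- et0
  d$wbal <- d$water_in - d$et0
  d
}

# balanced two-replicate plot table with known genotype means
toy_plots <- function(n_hybrids = 6, n_reps = 2, env = "2014_S01",
                      mu = 10, g_sd = 1, rep_sd = 0.5, res_sd = 0.3,
                      seed = 1) {
  set.seed(seed)
  g <- rnorm(n_hybrids, 0, g_sd)
  r <- rnorm(n_reps, 0, rep_sd)
  d <- expand.grid(hybrid = sprintf("H%02d", seq_len(n_hybrids)),
                   replicate = seq_len(n_reps),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$environment <- env
  d$site <- "S01"
  d$year <- 2014
  d$planting_date <- as.Date("2014-05-01")
  d$silking_date <- as.Date("2014-07-15")
  d$trait <- mu + g[match(d$hybrid, sprintf("H%02d", seq_len(n_hybrids)))] +
    r[d$replicate] + rnorm(nrow(d), 0, res_sd)
  attr(d, "g") <- g
  attr(d, "mu") <- mu
  d
}

# brute-force all-pairs LD pruning oracle using the same removal rule
ld_prune_oracle <- function(m, r2_max = 0.99) {
  p <- ncol(m)
  maf <- pmin(colMeans(m) / 2, 1 - colMeans(m) / 2)
  keep <- rep(TRUE, p)
  repeat {
    live <- which(keep)
    r2 <- suppressWarnings(stats::cor(m[, live, drop = FALSE]))^2
    r2[!is.finite(r2)] <- 0
    found <- FALSE
    for (a in seq_along(live)) {
      for (b in seq_along(live)) {
        if (b <= a) next
        if (r2[a, b] > r2_max) {
          i <- live[a]; j <- live[b]
          drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else
            max(i, j)
          keep[drop] <- FALSE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
  }
  colnames(m)[keep]
}
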