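test_that("stage windows use the 7/14/65-day offsets with half-open bounds", {
  w <- stage_windows(as.Date("2014-05-01"), as.Date("2014-07-15"))
  expect_equal(w$veg_start, as.Date("2014-05-01"))
  expect_equal(w$veg_end, as.Date("2014-07-08"))
  expect_equal(w$flw_end, as.Date("2014-07-29"))
  expect_equal(w$gf_end, as.Date("2014-10-02"))
  # union covers [planting, silking + 79) exactly, windows contiguous
  expect_equal(as.numeric(w$gf_end - w$veg_start),
               as.numeric(as.Date("2014-07-15") - as.Date("2014-05-01")) + 79)
  expect_equal(as.numeric(w$gf_end - w$flw_end), 65)
  expect_error(stage_windows(as.Date("2014-05-01"), as.Date("2014-05-08")),
               "silking")
})

test_that("stage covariates compute the 13 Table-style summaries per window", {
  w <- stage_windows(as.Date("2014-05-01"), as.Date("2014-07-15"))
  dates <- seq(w$veg_start, w$gf_end - 1, by = "day")
  d <- constant_daily(dates, tmin = 15, tmax = 25, prcp = 0)
  covs <- stage_covariates(d, w)
  expect_length(covs, 39)
  expect_equal(sum(endsWith(names(covs), ".V")), 13)
  expect_equal(unname(covs["FreqP5.V"]), 0)
  expect_equal(unname(covs["FreqMaxT30.F"]), 0)
  expect_equal(unname(covs["St30.G"]), 0)
  expect_equal(unname(covs["MeanT.V"]), 20)
  # hot flowering window: tmax 32 every day
  d2 <- d
  flw <- d2$date >= w$veg_end & d2$date < w$flw_end
  d2$tmax[flw] <- 32
  d2$gdd <- daily_growing_degrees(d2$tmin, d2$tmax, 10)
  covs2 <- stage_covariates(d2, w)
  expect_equal(unname(covs2["FreqMaxT30.F"]), 1)
  expect_equal(unname(covs2["St30.F"]), 32 * sum(flw))
  # additivity of the cumulative covariates
  expect_equal(unname(covs["CumSumET0.V"]), 4 * sum(d$date < w$veg_end))
  expect_equal(unname(covs["P.V"] + covs["P.F"] + covs["P.G"]), sum(d$prcp))
  # gap detection
  expect_error(stage_covariates(d[-10, ], w), "missing days")
})

test_that("the covariate registry enumerates 13 names x 3 stages plus 4 soil", {
  nm <- ec_covariate_names("grain_yield")
  expect_length(nm, 43)
  expect_equal(sum(grepl("\\.SC$", nm)), 4)
  base <- unique(sub("\\.(V|F|G)$", "", nm[!grepl("\\.SC$", nm)]))
  expect_length(base, 13)
  for (b in base) for (s in c("V", "F", "G"))
    expect_true(paste0(b, ".", s) %in% nm)
  nm_ph <- ec_covariate_names("plant_height")
  expect_length(nm_ph, 13 * 2 + 4)
  expect_false(any(grepl("\\.G$", setdiff(nm_ph, "OM.SC"))))
  expect_length(ec_covariate_names("grain_yield", coords = TRUE), 45)
})

make_cov_matrix <- function(n_obs = 12, seed = 5) {
  set.seed(seed)
  w <- stage_windows(as.Date("2014-05-01"), as.Date("2014-07-15"))
  dates <- seq(w$veg_start, w$gf_end - 1, by = "day")
  covs <- t(vapply(seq_len(n_obs), function(i) {
    d <- constant_daily(dates, tmin = 13 + i / 3 + rnorm(1, 0, 0.3),
                        tmax = 24 + i / 2 + rnorm(1, 0, 0.3),
                        prcp = abs(rnorm(1, 3, 2)))
    stage_covariates(d, w)
  }, numeric(39)))
  covs
}

test_that("W assembly applies trait masks, soil join and standardization", {
  covs <- make_cov_matrix()
  soil <- rbind(simulate_soil("A", 1), simulate_soil("B", 1))
  sites <- rep(c("A", "B"), each = 6)
  coords <- data.frame(longitude = rep(c(-95, -85), each = 6) +
                         rnorm(12, 0, 0.01),
                       latitude = rep(c(40, 42), each = 6) +
                         rnorm(12, 0, 0.01))
  W <- suppressWarnings(assemble_W(covs, soil, sites, coords, "grain_yield"))
  dropped <- 45 - ncol(W)  # zero-variance columns under constant weather
  expect_true(all(abs(colMeans(W)) < 1e-8))
  expect_true(all(abs(apply(W, 2, sd) - 1) < 1e-6))
  W_ph <- suppressWarnings(assemble_W(covs, soil, sites, NULL,
                                      "plant_height"))
  expect_false(any(grepl("\\.G$", colnames(W_ph))))
  expect_true(ncol(W_ph) <= 30)
  expect_error(assemble_W(covs, soil, rep("C", 12), NULL, "grain_yield"),
               "soil")
  # full column sets when every covariate varies
  covs2 <- covs
  covs2 <- covs2 + matrix(rnorm(length(covs2), 0, 1e-3), nrow(covs2))
  W_full <- assemble_W(covs2, soil, sites, coords, "grain_yield")
  expect_equal(ncol(W_full), 45)
  W_ph_full <- assemble_W(covs2, soil, sites, NULL, "plant_height")
  expect_equal(ncol(W_ph_full), 30)
})

test_that("train-only standardization maps test rows with train statistics", {
  covs <- make_cov_matrix()
  covs <- covs + matrix(rnorm(length(covs), 0, 1e-3), nrow(covs))
  soil <- rbind(simulate_soil("A", 1), simulate_soil("B", 1))
  sites <- rep(c("A", "B"), each = 6)
  tr <- 1:8
  W <- assemble_W(covs, soil, sites, NULL, "grain_yield", train_index = tr)
  expect_true(all(abs(colMeans(W[tr, ])) < 1e-8))
  # test rows are shifted by the same train-time transform
  ctr <- attr(W, "center"); scl <- attr(W, "scale")
  raw <- cbind(covs, SandProp.SC = soil$SandProp.SC[match(sites, soil$site)],
               Silt.Prop.SC = soil$Silt.Prop.SC[match(sites, soil$site)],
               ClayProp.SC = soil$ClayProp.SC[match(sites, soil$site)],
               OM.SC = soil$OM.SC[match(sites, soil$site)])
  j <- "MeanT.F"
  expect_equal(W[9, j], (raw[9, j] - ctr[j]) / scl[j], ignore_attr = TRUE)
})

test_that("environment PCA separates climatically distinct clusters", {
  set.seed(3)
  hot <- lapply(1:5, function(i)
    simulate_daily_series(climate_params(paste0("H", i), latitude = 34,
                                         t_mid = 17), 2015, seed = i))
  cool <- lapply(1:5, function(i)
    simulate_daily_series(climate_params(paste0("C", i), latitude = 45,
                                         t_mid = 9), 2015, seed = i + 50))
  rows <- lapply(c(hot, cool), function(d) {
    d <- derive_daily(d, 40, 200)
    w <- stage_windows(d$date[5], d$date[5] + 75)
    stage_covariates(d, w)
  })
  M <- do.call(rbind, rows)
  p <- environment_pca(M)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(p$variance_fraction) < 1e-12))
  pc1 <- p$scores[, 1]
  grp <- rep(c("hot", "cool"), each = 5)
  gap <- min(pc1[grp == "hot"]) > max(pc1[grp == "cool"]) ||
    min(pc1[grp == "cool"]) > max(pc1[grp == "hot"])
  expect_true(gap)  # PC1 fully separates the two climate clusters
  # duplicated environment rows get identical scores
  M2 <- rbind(M, M[1, , drop = FALSE])
  p2 <- environment_pca(M2)
  expect_equal(p2$scores[nrow(M2), ], p2$scores[1, ])
  expect_error(environment_pca(M[1:2, ]), "3 environments")
})
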