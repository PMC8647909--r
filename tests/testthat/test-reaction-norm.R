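test_that("model labels parse and interaction constituents are enforced", {
  sp <- parse_model_spec("G+E+W+GxW+GxE")
  expect_setequal(sp$main, c("G", "E", "W"))
  expect_setequal(sp$interactions, c("GxW", "GxE"))
  expect_error(parse_model_spec("G+E+GxW"), "requires main effects")
  expect_error(parse_model_spec("G+Q"), "unknown main")
})

test_that("kernels expand incidence structure and Hadamard products correctly", {
  sim <- small_sim()
  grm <- compute_grm(sim$hybrids)
  obs <- sim$obs[1:30, ]
  oid <- paste(obs$environment, obs$hybrid, sep = ":")
  W <- as.matrix(sim$W)[oid, ]
  fac <- data.frame(hybrid = obs$hybrid, environment = obs$environment,
                    site = obs$site, year = obs$year)
  kern <- build_kernels("G+E+S+Y+W+GxE+GxW", grm, W, fac)
  expect_equal(kern$GxE, kern$G * kern$E)
  expect_equal(kern$GxW, kern$G * kern$W)
  # same hybrid in two different environments: full genomic covariance,
  # zero environment covariance
  h <- fac$hybrid[1]
  js <- which(fac$hybrid == h)
  if (length(js) >= 2) {
    expect_equal(kern$G[js[1], js[2]], grm[h, h])
    expect_equal(kern$E[js[1], js[2]], 0)
  }
  # identical EC rows give identical Omega entries
  W2 <- W; W2[2, ] <- W2[1, ]
  kern2 <- build_kernels("G+E+W", grm, W2, fac)
  expect_equal(kern2$W[1, 1], kern2$W[2, 2])
  expect_equal(kern2$W[1, 1], kern2$W[1, 2])
  # Omega diagonal averages about one after standardization
  expect_equal(mean(diag(kern$W)), 1, tolerance = 0.2)
  # every kernel passes the PSD policy (Schur product theorem holds)
  for (k in names(kern))
    expect_silent(metGP:::kernel_eigen(kern[[k]], k))
  expect_error(build_kernels("G+E+GxW", grm, W, fac), "requires")
})

test_that("a constant response collapses the posterior onto the mean", {
  sim <- small_sim()
  grm <- compute_grm(sim$hybrids)
  obs <- sim$obs[1:40, ]
  fac <- data.frame(hybrid = obs$hybrid, environment = obs$environment,
                    site = obs$site, year = obs$year)
  kern <- build_kernels("G+E", grm, NULL, fac)
  y <- rep(3.5, 40)
  fit <- fit_gibbs(y, kern, iters = 600, burnin = 100, thin = 2, seed = 1)
  expect_equal(fit$mu, 3.5, tolerance = 0.05)
  expect_lt(max(fit$varcomp$mean), 0.01)
})

test_that("fixed-variance Gibbs agrees with the closed-form BLUP oracle", {
  set.seed(5)
  n <- 60
  sim <- small_sim()
  grm <- compute_grm(sim$hybrids)
  obs <- sim$obs[1:n, ]
  oid <- paste(obs$environment, obs$hybrid, sep = ":")
  fac <- data.frame(hybrid = obs$hybrid, environment = obs$environment,
                    site = obs$site, year = obs$year)
  kern <- build_kernels("G+E", grm, NULL, fac)
  y <- sim$plots$trait[match(oid, paste(sim$plots$environment,
                                        sim$plots$hybrid, sep = ":"))]
  vars <- list(G = 0.5, E = 0.8, sigma2_resid = 0.6)
  oracle <- blup_oracle(y, kern, vars)
  fit <- fit_gibbs(y, kern, iters = 21000, burnin = 1000, thin = 1,
                   seed = 2, fix_variances = vars)
  expect_lt(max(abs(fit$fitted - oracle$fitted)), 0.02 * sd(y))
  expect_gt(cor(fit$fitted, oracle$fitted), 0.999)
  expect_equal(fit$mu, oracle$mu, tolerance = 0.02 * sd(y))
})

test_that("the BLUP oracle reduces to known closed forms", {
  set.seed(8)
  n <- 40
  y <- rnorm(n, 5, 1)
  # all kernel variances -> 0: predictions collapse to the GLS mean
  K <- tcrossprod(matrix(rnorm(n * 3), n))
  K <- K / mean(diag(K))
  tiny <- blup_oracle(y, list(A = K), list(A = 1e-12, sigma2_resid = 1))
  expect_equal(unname(tiny$fitted), rep(mean(y), n), tolerance = 1e-4)
  # identity kernel: ridge regression closed form
  lam <- 0.7
  r <- blup_oracle(y, list(I = diag(n)),
                   list(I = lam, sigma2_resid = 1))
  mu <- r$mu
  expect_equal(r$effects$I, as.numeric(lam * solve((lam + 1) * diag(n),
                                                   y - mu)),
               tolerance = 1e-8)
  # dense generalized least squares solve agreement
  K2 <- tcrossprod(matrix(rnorm(n * 5), n)) / 5
  vars <- list(A = 0.6, B = 0.3, sigma2_resid = 0.5)
  or <- blup_oracle(y, list(A = K, B = K2), vars)
  V <- 0.6 * K + 0.3 * K2 + 0.5 * diag(n)
  one <- rep(1, n)
  mu_d <- sum(solve(V, y)) / sum(solve(V, one))
  expect_equal(or$mu, mu_d, tolerance = 1e-10)
  expect_equal(or$fitted,
               as.numeric(mu_d + (0.6 * K + 0.3 * K2) %*%
                            solve(V, y - mu_d)),
               tolerance = 1e-10)
  expect_error(blup_oracle(y, list(A = K), list(A = 1)), "sigma2_resid")
})

test_that("masked prediction flows through kernel covariance only", {
  sim <- small_sim()
  grm <- compute_grm(sim$hybrids)
  obs <- sim$obs[1:60, ]
  oid <- paste(obs$environment, obs$hybrid, sep = ":")
  fac <- data.frame(hybrid = obs$hybrid, environment = obs$environment,
                    site = obs$site, year = obs$year)
  W <- as.matrix(sim$W)[oid, ]
  y <- sim$plots$trait[match(oid, paste(sim$plots$environment,
                                        sim$plots$hybrid, sep = ":"))]
  kern <- build_kernels("G+E+W+GxW", grm, W, fac)
  vars <- list(G = 0.4, E = 0.8, W = 0.3, GxW = 0.3, sigma2_resid = 0.7)
  # a test row duplicating a train row's kernel profile predicts close to
  # that row's fitted value
  test_idx <- c(7, 19)
  p <- predict_masked("G+E+W+GxW", kern, y, test_idx, method = "blup",
                      variances = vars)
  full <- blup_oracle(y, kern, vars)
  twin <- which(fac$hybrid == fac$hybrid[7] &
                  fac$environment == fac$environment[7])
  expect_length(p, 2)
  # agreement between the gibbs path and the oracle path at fixed variances
  pg <- predict_masked("G+E+W+GxW", kern, y, test_idx, method = "gibbs",
                       fix_variances = vars, iters = 8000, burnin = 500,
                       thin = 1, seed = 3)
  expect_lt(max(abs(pg - p)), 0.05 * sd(y))
  # training fitted values barely move when masked rows are added
  ym <- y; ym[test_idx] <- NA
  fit_masked <- blup_oracle(ym, kern, vars)
  keep <- setdiff(seq_along(y), test_idx)
  sub <- blup_oracle(y[keep], lapply(kern, function(K) K[keep, keep]),
                     vars)
  expect_lt(max(abs(fit_masked$fitted[keep] - sub$fitted)), 1e-8)
})

test_that("posterior rank ordering of variance components tracks the truth", {
  # moderate-size single-seed check; the full multi-seed recovery study is
  # exercised by the acceptance suite
  cfg <- sim_config(n_sites = 4, n_years = 2, n_hybrids = 80, n_reps = 1,
                    prop_tested = 0.9,
                    variance_components = list(sigma2_E = 1.2, sigma2_S = 0,
                      sigma2_Y = 0, sigma2_g = 0.5, sigma2_w = 0.3,
                      sigma2_gw = 0.25, sigma2_gE = 0.2, sigma2_rep = 0,
                      sigma2_resid = 0.6),
                    seed = 17)
  sim <- suppressWarnings(simulate_met(cfg))
  obs <- sim$plots
  oid <- paste(obs$environment, obs$hybrid, sep = ":")
  W <- as.matrix(sim$W)[oid, ]
  grm <- compute_grm(sim$hybrids)
  fac <- data.frame(hybrid = obs$hybrid, environment = obs$environment,
                    site = obs$site, year = obs$year)
  kern <- build_kernels("G+E+W+GxW+GxE", grm, W, fac)
  fit <- fit_gibbs(obs$trait, kern, iters = 3000, burnin = 500, thin = 2,
                   seed = 17)
  est <- setNames(fit$varcomp$mean, fit$varcomp$component)
  truth <- c(E = 1.2, G = 0.5, W = 0.3, GxW = 0.25, GxE = 0.2,
             sigma2_resid = 0.6)
  rho <- cor(est[names(truth)], truth, method = "spearman")
  expect_gte(rho, 0.6)
  expect_true(all(fit$varcomp$mean >= 0))
  expect_true(all(is.finite(fit$ess)))
})
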