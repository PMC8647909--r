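test_that("biallelic filter drops markers with extra alleles", {
  m <- matrix(c(0, 2, 1, 0, 2, 2), 2, 3,
              dimnames = list(c("a", "b"), c("m1", "m2", "m3")))
  out <- filter_biallelic(m, c(2, 3, 2))
  expect_equal(colnames(out), c("m1", "m3"))
  expect_identical(filter_biallelic(m, c(2, 2, 2)), m)
  set.seed(1)
  big <- matrix(rbinom(50 * 200, 2, 0.3), 50, 200,
                dimnames = list(NULL, paste0("M", 1:200)))
  ac <- rep(2L, 200); ac[sample(200, 20)] <- 3L  # 10% multi-allelic
  expect_equal(ncol(filter_biallelic(big, ac)) / 200, 0.9)
})

test_that("taxa filter applies the coverage and heterozygosity boundaries", {
  p <- 100
  m <- rbind(
    ok = c(rep(0, 50), rep(2, 50)),
    low_cov = c(rep(NA, 31), rep(0, 69)),          # 69% coverage
    edge_cov = c(rep(NA, 30), rep(2, 70)),         # exactly 70%
    high_het = c(rep(1, 9), rep(0, 91)),           # 9% heterozygous
    edge_het = c(rep(1, 8), rep(2, 92)))           # exactly 8%
  out <- filter_taxa(m)
  expect_setequal(rownames(out), c("ok", "edge_cov", "edge_het"))
  expect_identical(filter_taxa(m[c("ok", "edge_het"), ]),
                   m[c("ok", "edge_het"), ])
  expect_error(filter_taxa(m["low_cov", , drop = FALSE]), "all taxa")
})

test_that("parent marker filter removes monomorphic, missing/het and low-MAF loci", {
  n <- 100
  mk <- function(x) x
  m <- cbind(
    mono = rep(2, n),
    miss6 = c(rep(NA, 6), rbinom(n - 6, 1, 0.5) * 2),   # 6% missing
    het6 = c(rep(1, 6), rbinom(n - 6, 1, 0.5) * 2),     # 6% heterozygous
    maf1 = c(rep(2, n - 1), 0),                         # MAF 1%
    maf3 = c(rep(2, n - 6), rep(0, 6)),                 # MAF 3%
    good = rbinom(n, 1, 0.4) * 2)
  out <- filter_parent_markers(m)
  expect_true(all(c("maf3", "good") %in% colnames(out)))
  expect_false(any(c("mono", "miss6", "het6", "maf1") %in% colnames(out)))
})

test_that("mode imputation preserves observed calls and fills the mode", {
  m <- cbind(a = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2),
             b = c(2, 2, 0, 0, 2, 2, 2, 0, 2, 2))
  expect_identical(impute_missing(m), m)
  m2 <- m; m2[3, "a"] <- NA
  out <- impute_missing(m2)
  expect_equal(unname(out[3, "a"]), 0)  # mode of {0 x 8, 2 x 1}
  expect_equal(out[-3, ], m[-3, ])
  m3 <- m; m3[, "a"] <- NA
  expect_error(impute_missing(m3), "fully missing")
  # mask-and-restore: concordance beats the marginal guessing baseline
  sim <- small_sim()
  full <- impute_missing(attr(sim$inbreds, "clean"))
  set.seed(42)
  idx <- which(!is.na(full))
  hide <- sample(idx, round(0.05 * length(idx)))
  masked <- full; masked[hide] <- NA
  rest <- impute_missing(masked)
  conc <- mean(rest[hide] == full[hide])
  # random-guess baseline: drawing dosages from the panel-wide marginal
  marg <- table(full) / length(full)
  base <- sum(marg^2)
  expect_gt(conc, base)
  expect_gt(conc, 0.6)
})

test_that("LD pruning removes duplicates and matches the all-pairs oracle", {
  set.seed(9)
  base <- matrix(rbinom(40 * 6, 2, 0.4), 40, 6)
  dup <- cbind(base, base[, 3])
  colnames(dup) <- paste0("M", 1:7)
  out <- ld_prune(dup, window = 10, step = 2)
  expect_equal(sum(colnames(out) %in% c("M3", "M7")), 1)
  # mutually near-independent markers unchanged
  set.seed(10)
  ind <- matrix(rbinom(200 * 12, 2, 0.5), 200, 12,
                dimnames = list(NULL, paste0("I", 1:12)))
  expect_true(max(cor(ind)[upper.tri(diag(12))]^2) < 0.5)
  expect_identical(ld_prune(ind), ind)
  # 200-marker blocked fixture vs quadratic oracle
  cfg <- sim_config(n_inbreds = 40, n_markers = 200, het_rate = 0,
                    missing_rate = 0, seed = 31)
  m <- simulate_inbred_genotypes(cfg)
  m <- m[, apply(m, 2, var) > 0]
  kept <- colnames(ld_prune(m))
  expect_identical(kept, ld_prune_oracle(m))
})

test_that("hybrid construction averages parents and applies the panel MAF filter", {
  parents <- rbind(P1 = c(0, 2, 2, 0),
                   P2 = c(2, 2, 0, 0),
                   P3 = c(2, 2, 2, 2))
  colnames(parents) <- paste0("M", 1:4)
  ped <- data.frame(hybrid = c("H1", "H2"), parent1 = c("P1", "P2"),
                    parent2 = c("P2", "P3"))
  h <- build_hybrid_genotypes(parents, ped, maf_min = 0)
  expect_equal(unname(h["H1", "M1"]), 1)   # parents 0 and 2
  expect_equal(unname(h["H1", "M2"]), 2)   # parents 2 and 2
  expect_equal(unname(h["H2", "M4"]), 1)
  # near-fixed marker dropped by the hybrid-panel MAF filter
  set.seed(2)
  P <- matrix(2, 60, 50, dimnames = list(paste0("P", 1:60),
                                         paste0("M", 1:50)))
  P[, 1:48] <- rbinom(60 * 48, 1, 0.4) * 2
  P[1, 49] <- 0                        # rare allele -> hybrid MAF < 2%
  ped2 <- data.frame(hybrid = paste0("H", 1:30),
                     parent1 = paste0("P", 1:30),
                     parent2 = paste0("P", 31:60))
  h2 <- build_hybrid_genotypes(P, ped2, maf_min = 0.02)
  expect_false("M49" %in% colnames(h2))
  expect_false("M50" %in% colnames(h2))  # monomorphic
  expect_error(build_hybrid_genotypes(parents,
                                      data.frame(hybrid = "H9",
                                                 parent1 = "P1",
                                                 parent2 = "PX")),
               "unknown parent")
})

test_that("the GRM is centered, scaled and positive semidefinite", {
  sim <- small_sim()
  G <- compute_grm(sim$hybrids)
  n <- nrow(G)
  expect_lt(abs(sum(G)), 1e-6 * n^2)
  expect_equal(mean(diag(G)), (n - 1) / n, tolerance = 1e-10)
  expect_equal(G, t(G))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # duplicated sample: matching diagonal and off-diagonal entries
  m <- rbind(sim$hybrids, dup = sim$hybrids[1, ])
  G2 <- compute_grm(m)
  expect_equal(G2[1, 1], G2[nrow(m), nrow(m)])
  expect_equal(G2[1, 1], G2[1, nrow(m)])
  expect_error(compute_grm(matrix(2, 4, 3)), "no polymorphic")
})

test_that("marker principal components are orthogonal with a fixed sign convention", {
  sim <- small_sim()
  pcs <- marker_pcs(sim$hybrids, 5)
  cp <- crossprod(pcs)
  expect_true(all(abs(cp[upper.tri(cp)]) < 1e-8))
  vf <- attr(pcs, "variance_fraction")
  expect_true(all(diff(vf) < 1e-12))
  # rank-1 fixture: PC1 carries all the variance
  set.seed(4)
  u <- rnorm(30)
  r1 <- outer(u, rnorm(20))
  p1 <- marker_pcs(r1 + 0, 1)
  expect_equal(attr(p1, "variance_fraction")[1], 1, tolerance = 1e-8)
  expect_error(marker_pcs(sim$hybrids, 10000), "exceeds")
})

test_that("the pipeline applies filters in the canonical order and logs counts", {
  sim <- small_sim()
  out <- geno_pipeline(sim$inbreds, sim$pedigree,
                       allele_counts = attr(sim$inbreds, "allele_counts"))
  expect_equal(out$log$step,
               c("biallelic", "taxa", "parent_markers", "impute",
                 "ld_prune", "hybrids"))
  expect_true(all(diff(out$log$markers[1:5]) <= 0))
  expect_false(anyNA(out$parents))
  expect_false(anyNA(out$hybrids))
  expect_equal(nrow(out$grm), nrow(out$hybrids))
})
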