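# Standardized-genotype PCA and the moderated PC-geography correlation model.

test_that("PC1 separates two populations with disjoint frequencies", {
  set.seed(71)
  n <- 60; m <- 400
  p1 <- runif(m, 0.05, 0.25); p2 <- runif(m, 0.75, 0.95)
  X <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
    matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m)
  )
  map <- data.frame(chrom = 1L, id = paste0("s", 1:m), pos = 1:m * 1000,
                    a1 = "A", a2 = "C")
  pca <- standardized_pca(genotype_matrix(X, map), k = 2)
  grp <- rep(1:2, each = n / 2)
  expect_true(all(tapply(sign(pca$scores[, 1]), grp,
                         function(s) length(unique(s))) == 1))
  expect_true(sign(pca$scores[1, 1]) != sign(pca$scores[n, 1]))
})

test_that("PCA scores are centered, orthogonal, with ordered eigenvalues", {
  dm <- default_deme_map()
  fam <- simulate_families(200, seed = 72, deme_map = dm)
  sim <- simulate_genotypes(fam, build_snp_map(2, 500, 30e6), seed = 73,
                            deme_map = dm)
  pca <- standardized_pca(sim$genotypes, k = 4)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-8)
  cp <- crossprod(pca$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_error(standardized_pca(sim$genotypes, k = 300), "k exceeds")
})

test_that("PCA is sign-invariant to allele relabeling", {
  dm <- default_deme_map()
  fam <- simulate_families(100, seed = 74, deme_map = dm)
  sim <- simulate_genotypes(fam, build_snp_map(1, 400, 30e6), seed = 75,
                            deme_map = dm)
  G <- sim$genotypes
  Gflip <- genotype_matrix(2L - G$calls, G$map)
  p1 <- standardized_pca(G, 2)
  p2 <- standardized_pca(Gflip, 2)
  for (k in 1:2)
    expect_gt(abs(cor(p1$scores[, k], p2$scores[, k])), 1 - 1e-6)
})

test_that("PC1 tracks latitude under a cline and nothing without one", {
  dm <- default_deme_map()
  fam <- simulate_families(1000, seed = 76, deme_map = dm)
  sim <- simulate_genotypes(fam, build_snp_map(2, 1000, 30e6), seed = 77,
                            deme_map = dm)
  pca <- standardized_pca(sim$genotypes, 2)
  expect_gt(max(abs(cor(pca$scores[, 1], fam$o_lat)),
                abs(cor(pca$scores[, 1], fam$o_lon))), 0.5)

  sim0 <- simulate_genotypes(fam, build_snp_map(2, 1000, 30e6), seed = 77,
                             cline_strength = c(0, 0), deme_map = dm)
  pca0 <- standardized_pca(sim0$genotypes, 2)
  for (k in 1:2) {
    expect_lt(abs(cor(pca0$scores[, k], fam$o_lat)), 0.1)
    expect_lt(abs(cor(pca0$scores[, k], fam$o_lon)), 0.1)
  }
})

test_that("corr_pc_geo basics", {
  x <- rnorm(100)
  expect_equal(corr_pc_geo(x, x), 1.0)
  expect_equal(corr_pc_geo(x, -x), -1.0)
  set.seed(78)
  expect_lt(abs(corr_pc_geo(rnorm(10000), rnorm(10000))), 0.03)
  expect_error(corr_pc_geo(rep(1, 10), rnorm(10)), "constant")
  expect_error(corr_pc_geo(c(1, 2), c(1, 2)), "3 complete")
})

test_that("moderated fit: identical groups give lrt_stat exactly zero", {
  set.seed(79)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  d <- data.frame(x = rep(x, 4), y = rep(y, 4), g = rep(0:3, each = 200))
  fit <- moderated_correlation_fit(d$x, d$y, d$g)
  expect_equal(fit$lrt_stat, 0)
  expect_equal(fit$rho1, 0)
  expect_gte(fit$loglik_full, fit$loglik_null)
})

test_that("free-moments two-group fit reproduces sample correlations", {
  set.seed(80)
  d <- simulate_modcorr_data(300, rho0 = 0.2, rho1 = 0.35, n_groups = 2)
  d$x[d$g == 1] <- d$x[d$g == 1] * 3 + 5   # distinct group moments
  fit <- moderated_correlation_fit(d$x, d$y, d$g, free_moments = TRUE)
  r_obs <- vapply(0:1, function(g) cor(d$x[d$g == g], d$y[d$g == g]),
                  numeric(1))
  # with per-group moments and two groups the trend model is saturated in
  # rho, so fitted group correlations equal the MLE = sample correlations
  # (up to the n vs n-1 variance convention, absorbed by the correlation)
  expect_equal(unname(fit$rho_by_group), r_obs, tolerance = 2e-3)
})

test_that("moderated fit recovers a correlation trend and its null", {
  set.seed(81)
  # recovery at the study's trend: rho_g = 0.7 - 0.06 g
  hits <- 0; reps <- 20
  for (r in 1:reps) {
    d <- simulate_modcorr_data(400, 0.7, -0.06, seed = 8100 + r)
    fit <- moderated_correlation_fit(d$x, d$y, d$g)
    if (abs(fit$rho1 - (-0.06)) <= 2 * fit$se_rho1) hits <- hits + 1
  }
  expect_gte(hits, 0.85 * reps)

  # nesting always holds
  d <- simulate_modcorr_data(100, 0.5, 0, seed = 82)
  fit <- moderated_correlation_fit(d$x, d$y, d$g)
  expect_gte(fit$loglik_full, fit$loglik_null)
  expect_error(
    moderated_correlation_fit(d$x[1:16], d$y[1:16], rep(0:3, each = 4)),
    "at least 10")
})
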