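# Deme grid, family simulator, and genotype simulator.

test_that("deme grid geometry matches its declared spacing", {
  one <- build_deme_map(1, 1, 10, origin = c(52.0, 5.0))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$lat, one$lon), c(52.0, 5.0))

  two <- build_deme_map(2, 1, 10, origin = c(52.0, 5.0))
  d <- great_circle_km(two$lat[1], two$lon[1], two$lat[2], two$lon[2])
  expect_lt(abs(d - 10) / 10, 0.01)

  big <- build_deme_map(10, 10, 15, origin = c(51.0, 4.5))
  expect_equal(nrow(big), 100)
  # bounding-box span ~ 135 km per axis
  span_ns <- great_circle_km(min(big$lat), big$lon[1], max(big$lat), big$lon[1])
  expect_lt(abs(span_ns - 135) / 135, 0.01)
  row1 <- big[big$iy == 1, ]
  span_ew <- great_circle_km(row1$lat[1], min(row1$lon),
                             row1$lat[1], max(row1$lon))
  expect_lt(abs(span_ew - 135) / 135, 0.01)
  # every adjacent pair within 1%
  for (iy in c(1, 5, 10)) {
    r <- big[big$iy == iy, ]
    d <- great_circle_km(r$lat[-nrow(r)], r$lon[-nrow(r)],
                         r$lat[-1], r$lon[-1])
    expect_true(all(abs(d - 15) / 15 < 0.01))
  }
  expect_error(build_deme_map(0, 5, 10), "positive")
  expect_error(build_deme_map(2, 2, -1), "positive")
})

test_that("spousal assortment hits its Spearman target", {
  dm <- default_deme_map()
  f0 <- simulate_families(5000, assortment_rho = 0, seed = 11, deme_map = dm)
  expect_lt(abs(spearman_midrank(f0$father_ea, f0$mother_ea)), 0.05)

  f66 <- simulate_families(5000, assortment_rho = 0.66, seed = 12,
                           deme_map = dm)
  rho <- spearman_midrank(f66$father_ea, f66$mother_ea)
  expect_gt(rho, 0.61); expect_lt(rho, 0.71)

  # parent-offspring correlation target
  rho_po <- spearman_midrank(f66$father_ea, f66$offspring_ea)
  expect_gt(rho_po, 0.35); expect_lt(rho_po, 0.45)

  expect_error(simulate_families(100, assortment_rho = 1, deme_map = dm),
               "unreachable")
})

test_that("spouse Spearman rho is monotone in the assortment target", {
  dm <- default_deme_map()
  rhos <- vapply(c(0, 0.4, 0.8), function(r) {
    f <- simulate_families(5000, assortment_rho = r, seed = 13, deme_map = dm)
    spearman_midrank(f$father_ea, f$mother_ea)
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("migration distances match the EA-specific means", {
  dm <- default_deme_map()
  mig <- c(19.2, 16.3, 28.7, 49.8)
  fam <- add_birthplace_distances(
    simulate_families(5000, migration_km_by_ea = mig, seed = 14,
                      deme_map = dm))
  by_ea <- tapply(fam$dist_fo_km, fam$father_ea, mean)
  expect_true(all(abs(by_ea - mig) / mig < 0.15))
  by_ea_m <- tapply(fam$dist_mo_km, fam$mother_ea, mean)
  expect_true(all(abs(by_ea_m - mig) / mig < 0.15))
})

test_that("EA marginals match within binomial sampling error", {
  dm <- default_deme_map()
  marg <- c(0.2, 0.3, 0.3, 0.2)
  fam <- simulate_families(5000, ea_marginals = marg, seed = 15,
                           deme_map = dm)
  obs <- as.numeric(table(factor(fam$father_ea, 1:4))) / 5000
  se <- sqrt(marg * (1 - marg) / 5000)
  expect_true(all(abs(obs - marg) < 4 * se))
})

test_that("family table is reproducible and structurally valid", {
  dm <- default_deme_map()
  a <- simulate_families(500, seed = 16, deme_map = dm)
  b <- simulate_families(500, seed = 16, deme_map = dm)
  expect_identical(a, b)
  expect_true(validate_family_table(a, dm))
})

test_that("HBD fraction has expectation phi/2 and vanishes when phi0 = 0", {
  dm <- default_deme_map()
  fam <- simulate_families(500, seed = 17, deme_map = dm)
  # d = 0 forced by putting both parents at the offspring birthplace
  fam$f_lat <- fam$o_lat; fam$f_lon <- fam$o_lon
  fam$m_lat <- fam$o_lat; fam$m_lon <- fam$o_lon
  snp_map <- build_snp_map(2, 400, 30e6)
  sim <- simulate_genotypes(fam, snp_map, kinship_kernel = c(0.1, 50),
                            seed = 18, deme_map = dm)
  frac <- hbd_fraction(sim$truth)
  expect_lt(abs(mean(frac) - 0.05) / 0.05, 0.2)

  sim0 <- simulate_genotypes(fam, snp_map, kinship_kernel = c(0, 50),
                             seed = 18, deme_map = dm)
  expect_equal(nrow(sim0$truth$segments), 0)
  expect_error(simulate_genotypes(fam, snp_map[0, ], seed = 1), "empty")
})

test_that("true HBD fraction decreases with parental birthplace distance", {
  dm <- default_deme_map()
  fam <- add_birthplace_distances(simulate_families(800, seed = 19,
                                                    deme_map = dm))
  sim <- simulate_genotypes(fam, build_snp_map(2, 200, 30e6), seed = 20,
                            deme_map = dm)
  frac <- hbd_fraction(sim$truth)
  bin <- cut(fam$dist_fm_km, c(-1, 15, 45, 1e9))
  means <- tapply(frac, bin, mean)
  expect_true(all(diff(means) < 0))
})

test_that("genotype simulation is bit-identical under a fixed seed", {
  dm <- default_deme_map()
  fam <- simulate_families(50, seed = 21, deme_map = dm)
  sm <- build_snp_map(1, 300, 30e6)
  a <- simulate_genotypes(fam, sm, seed = 22, deme_map = dm)
  b <- simulate_genotypes(fam, sm, seed = 22, deme_map = dm)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth$segments, b$truth$segments)
})
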