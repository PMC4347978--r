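# Contingency chi-square, Spearman with midranks, migration ANOVA and
# consecutive-level t-tests.

test_that("chi-square is zero under exact independence", {
  rows <- c(10, 20, 30, 40); cols <- c(25, 25, 25, 25)
  O <- outer(rows, cols) / sum(rows)
  res <- contingency_chi2(O)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_equal(res$expected, O, ignore_attr = TRUE)
})

test_that("chi-square equals the brute-force cell sum on the spouse table", {
  O <- spouse_ea_crosstab()
  res <- contingency_chi2(O)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$expected, E, ignore_attr = TRUE)
  # margins of expected match observed margins
  expect_equal(rowSums(res$expected), rowSums(O), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colSums(res$expected), colSums(O), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(contingency_chi2(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(contingency_chi2(matrix(1:4, 1)), "2x2")
})

test_that("Spearman midranks: table form equals the expanded pair list", {
  O <- spouse_ea_crosstab()
  f <- rep(rep(1:4, each = 4), as.vector(t(O)))
  m <- rep(rep(1:4, times = 4), as.vector(t(O)))
  expect_equal(spearman_midrank(table = O), spearman_midrank(f, m),
               tolerance = 1e-12)

  diag_only <- diag(c(5, 10, 15, 20))
  expect_equal(spearman_midrank(table = diag_only), 1.0)
  expect_error(spearman_midrank(rep(1, 10), 1:10), "constant")

  set.seed(51)
  x <- sample(1:4, 10000, replace = TRUE)
  y <- sample(1:4, 10000, replace = TRUE)
  expect_lt(abs(spearman_midrank(x, y)), 0.03)
})

test_that("ANOVA recovers the one-way decomposition", {
  # null case: identical generating distribution in all groups -> F ~ 1
  set.seed(52)
  fs <- replicate(200, {
    v <- rgamma(200, 1, 1 / 25)
    anova_by_level(v, sample(1:4, 200, replace = TRUE))$F
  })
  expect_lt(abs(mean(fs) - 1), 0.25)

  # two-group case: F equals t^2 (pooled)
  set.seed(53)
  v <- c(rnorm(30, 0), rnorm(40, 1))
  lv <- rep(1:2, c(30, 40))
  an <- anova_by_level(v, lv)
  tt <- consecutive_level_ttests(v, lv)
  expect_equal(an$F, tt$t^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p, tolerance = 1e-10)

  expect_error(anova_by_level(rnorm(10), rep(1, 10)), "2 non-empty")
  expect_warning(anova_by_level(c(rnorm(20), 5), c(rep(1:2, 10), 3)),
                 "excluding")
})

test_that("migration-distance separation is detected at study effect sizes", {
  # gamma-distributed distances matched to the paternal migration table
  means <- c(19.2, 16.3, 28.7, 49.8)
  sds <- c(32.4, 30.8, 46.0, 55.3)
  ns <- c(172, 512, 291, 375)
  set.seed(54)
  anova_sig <- 0; t34_sig <- 0
  reps <- 100
  for (r in 1:reps) {
    v <- unlist(lapply(1:4, function(g) {
      shape <- (means[g] / sds[g])^2
      rgamma(ns[g], shape = shape, rate = shape / means[g])
    }))
    lv <- rep(1:4, ns)
    if (anova_by_level(v, lv)$p < 1e-10) anova_sig <- anova_sig + 1
    tt <- consecutive_level_ttests(v, lv)
    if (tt$p[tt$level_a == 3] < 0.001) t34_sig <- t34_sig + 1
  }
  expect_gte(anova_sig, 0.95 * reps)
  expect_gte(t34_sig, 0.95 * reps)
})

test_that("consecutive t-tests: identical samples and antisymmetry", {
  x <- rep(c(1.0, 2.0, 3.0), 10)
  v <- c(x, x); lv <- rep(1:2, each = 30)
  tt <- consecutive_level_ttests(v, lv)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  set.seed(55)
  a <- rnorm(30, 0); b <- rnorm(30, 2)
  fwd <- consecutive_level_ttests(c(a, b), rep(1:2, each = 30))
  rev <- consecutive_level_ttests(c(b, a), rep(1:2, each = 30))
  expect_equal(fwd$t, -rev$t, tolerance = 1e-12)

  expect_warning(consecutive_level_ttests(c(rnorm(20), 1),
                                          c(rep(1, 20), 2)), "skipping")

  # Welch variant differs under unequal variances
  set.seed(56)
  v2 <- c(rnorm(20, 0, 1), rnorm(60, 0.5, 4))
  l2 <- rep(1:2, c(20, 60))
  tp <- consecutive_level_ttests(v2, l2, var_equal = TRUE)
  tw <- consecutive_level_ttests(v2, l2, var_equal = FALSE)
  expect_false(isTRUE(all.equal(tp$p, tw$p)))
})
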