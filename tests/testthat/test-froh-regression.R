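# OLS, permutation R-squared change, Sobel mediation.

test_that("OLS basics: perfect fit, standardized betas, rank checks", {
  set.seed(61)
  x <- rnorm(100)
  fit <- ols(x * 3 + 2, data.frame(x = x))
  expect_equal(unname(fit$beta_std["x"]), 1.0, tolerance = 1e-10)
  expect_equal(fit$r2, 1.0, tolerance = 1e-10)

  # standardized betas invariant to linear rescaling of predictors
  X <- data.frame(a = rnorm(200), b = rnorm(200))
  y <- X$a - 2 * X$b + rnorm(200)
  f1 <- ols(y, X)
  f2 <- ols(y, data.frame(a = X$a * 100 + 5, b = X$b / 3))
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-10)

  expect_error(ols(y, cbind(X, c = X$a)), "collinear.*c|c.*collinear")
  expect_error(ols(y, cbind(X, k = 1)), "constant")
  expect_error(ols(rnorm(3), X[1:3, ]), "n > p")
})

test_that("OLS matches a QR reference solution", {
  set.seed(62)
  for (i in 1:20) {
    n <- 150; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    fit <- ols(as.numeric(y), as.data.frame(X))
    ref <- qr.coef(qr(cbind(1, X)), y)
    expect_equal(unname(fit$beta), unname(ref[-1]), tolerance = 1e-8)
  }
})

test_that("null R-squared has expectation p / (n - 1)", {
  set.seed(63)
  n <- 500; p <- 6
  r2s <- replicate(300, {
    ols(rnorm(n), as.data.frame(matrix(rnorm(n * p), n, p)))$r2
  })
  expect_lt(abs(mean(r2s) - p / (n - 1)) / (p / (n - 1)), 0.15)
})

test_that("R-squared change of a redundant predictor is zero", {
  set.seed(64)
  Xb <- data.frame(a = rnorm(300), b = rnorm(300))
  y <- Xb$a + rnorm(300)
  pt <- r2_change_perm_test(y, Xb, Xb$a, n_perm = 200, seed = 1)
  expect_equal(pt$r2_change, 0, tolerance = 1e-12)
  expect_gt(pt$empirical_p, 0.9)
})

test_that("observed R-squared change is seed-invariant; only p varies", {
  set.seed(65)
  Xb <- data.frame(a = rnorm(400))
  x_new <- rnorm(400)
  y <- Xb$a + 0.6 * x_new + rnorm(400)
  p1 <- r2_change_perm_test(y, Xb, x_new, n_perm = 300, seed = 1)
  p2 <- r2_change_perm_test(y, Xb, x_new, n_perm = 300, seed = 2)
  expect_identical(p1$r2_change, p2$r2_change)
  # r2_change matches the two-lm definition
  full <- ols(y, cbind(Xb, x_new = x_new))
  base <- ols(y, Xb)
  expect_equal(p1$r2_change, full$r2 - base$r2, tolerance = 1e-10)
  expect_gte(p1$r2_change, 0)
  # add-one convention never returns zero; rank convention can
  p3 <- r2_change_perm_test(y, Xb, x_new, n_perm = 300, seed = 1,
                            convention = "rank")
  expect_equal(p3$empirical_p, 0)
  expect_equal(p1$empirical_p, 1 / 301)
  expect_warning(r2_change_perm_test(y, Xb, x_new, n_perm = 50, seed = 1),
                 "coarse")
  expect_error(r2_change_perm_test(y, Xb, x_new, n_perm = 0), "positive")
})

test_that("Sobel path algebra: tau = tau' + alpha*beta to 1e-8", {
  set.seed(66)
  for (i in 1:20) {
    d <- simulate_mediation_data(300, alpha = runif(1, -0.3, 0.3),
                                 beta = runif(1, -0.3, 0.3),
                                 tau_prime = runif(1, -0.2, 0.2), seed = i)
    st <- sobel_test(d$x, d$m, d$y,
                     covariates = d[, c("pc1", "pc2", "pc3", "religion",
                                        "city")])
    expect_equal(st$tau, st$tau_prime + st$alpha * st$beta,
                 tolerance = 1e-8)
    expect_equal(sign(st$sobel_z), sign(st$alpha * st$beta))
  }
})

test_that("Sobel z is near zero when the outcome ignores the mediator", {
  set.seed(67)
  zs <- replicate(50, {
    d <- simulate_mediation_data(400, alpha = 0.3, beta = 0,
                                 tau_prime = 0.2, seed = sample.int(1e6, 1))
    sobel_test(d$x, d$m, d$y)$sobel_z
  })
  expect_lt(abs(mean(zs)), 0.3)
  expect_lt(mean(abs(zs) > 1.96), 0.15)
  expect_error(sobel_test(1:10, rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("mediation discriminates direct-only from mediated effects", {
  set.seed(68)
  direct_ok <- 0
  reps <- 25
  for (r in 1:reps) {
    d <- simulate_mediation_data(2000, alpha = 0, beta = 0,
                                 tau_prime = 0.15, seed = 7000 + r)
    st <- sobel_test(d$x, d$m, d$y,
                     covariates = d[, c("pc1", "pc2", "pc3", "religion",
                                        "city")])
    if (st$sobel_p > 0.05 && st$tau_prime_p < 0.01) direct_ok <- direct_ok + 1
  }
  expect_gte(direct_ok, 0.8 * reps)
})
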