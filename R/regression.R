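# OLS with standardized betas, the permutation test for the R-squared
# change of a nested regression, and the Sobel / full mediation tests.

#' Ordinary least squares with standardized coefficients
#'
#' Least-squares fit of `y` on the columns of `X` (intercept added), with
#' standardized betas (coefficients of the fit on z-scored outcome and
#' predictors), two-sided t p-values, and R-squared. Rank-deficient design
#' matrices are rejected naming the collinear columns; constant predictors
#' are rejected.
#'
#' @param y Numeric outcome vector.
#' @param X Data frame or matrix of predictors.
#' @return List (`regression_result`): `beta` (raw), `beta_std`, `se`, `t`,
#'   `p` per predictor, `r2`, `n`, `sigma`.
#' @export
ols <- function(y, X) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(names(X)[sds == 0], collapse = ", "), call. = FALSE)
  if (stats::sd(y) == 0)
    stop("outcome has zero variance", call. = FALSE)
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qx <- qr(M)
  if (qx$rank < ncol(M)) {
    bad <- colnames(M)[qx$pivot[(qx$rank + 1):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(M, y)
  res <- fit$residuals
  df <- n - ncol(M)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- stats::setNames(sqrt(diag(XtXinv) * sigma2), colnames(M))
  tstat <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  beta <- fit$coefficients[-1]
  structure(list(
    beta = beta,
    beta_std = beta * sds / stats::sd(y),
    se = se[-1], t = tstat[-1], p = pval[-1],
    r2 = r2, n = n, sigma = sqrt(sigma2)
  ), class = "regression_result")
}

# R^2 of y regressed on a thin Q basis that includes the intercept:
# ||Q'y||^2 minus the intercept projection, over total sum of squares.
.qr_q <- function(X) {
  M <- cbind(1, as.matrix(X))
  qx <- qr(M)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

#' Permutation test for the R-squared change of a nested regression
#'
#' Observed statistic: `R2(X_base + x_new) - R2(X_base)` for the outcome
#' `y`. Null distribution: the outcome is randomly permuted across samples
#' `n_perm` times and the R-squared change recomputed each time (covariates
#' stay attached to the samples, so the null preserves the covariate
#' structure of the design). The empirical p-value defaults to the
#' add-one convention `(# null >= observed + 1) / (n_perm + 1)`, which
#' cannot return an exact zero; `convention = "rank"` divides the plain
#' exceedance count by `n_perm` (the convention under which a p-value below
#' the Monte-Carlo resolution prints as < 1/n_perm).
#'
#' @param y Outcome vector.
#' @param X_base Covariate-only design (data frame/matrix).
#' @param x_new Added predictor (vector or single-column object).
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed for the permutations.
#' @param convention `"add_one"` (default) or `"rank"`.
#' @return List (`permutation_result`): `r2_change`, `empirical_p`,
#'   `r2_base`, `r2_full`, `n_perm`, `n`, `seed`, `null_quantiles`.
#' @export
r2_change_perm_test <- function(y, X_base, x_new, n_perm = 100000,
                                seed = NULL,
                                convention = c("add_one", "rank")) {
  convention <- match.arg(convention)
  if (n_perm <= 0) stop("n_perm must be positive", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: empirical p is very coarse",
                            call. = FALSE)
  x_new <- as.numeric(as.matrix(x_new))
  X_base <- as.data.frame(X_base)
  ok <- stats::complete.cases(y, X_base, x_new)
  y <- y[ok]; X_base <- X_base[ok, , drop = FALSE]; x_new <- x_new[ok]
  n <- length(y)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss == 0) stop("outcome has zero variance", call. = FALSE)

  Qb <- .qr_q(X_base)
  Qf <- .qr_q(cbind(X_base, x_new = x_new))
  # y is centered, so ||Q'y||^2 on a basis containing the intercept is the
  # model sum of squares directly
  proj2 <- function(Q, Y) colSums(crossprod(Q, Y)^2)
  r2_base <- proj2(Qb, matrix(yc, n)) / tss
  r2_full <- proj2(Qf, matrix(yc, n)) / tss
  obs <- r2_full - r2_base

  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  chunk <- max(1L, min(n_perm, floor(2e7 / n)))
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Yp <- matrix(yc[sample.int(n)], n, b)
    if (b > 1) for (j in 2:b) Yp[, j] <- yc[sample.int(n)]
    d <- (proj2(Qf, Yp) - proj2(Qb, Yp)) / tss
    exceed <- exceed + sum(d >= obs)
    done <- done + b
  }
  p <- if (convention == "add_one") (exceed + 1) / (n_perm + 1)
       else exceed / n_perm
  structure(list(r2_change = unname(obs), empirical_p = p,
                 r2_base = unname(r2_base), r2_full = unname(r2_full),
                 n_perm = n_perm, n = n, seed = seed,
                 convention = convention),
            class = "permutation_result")
}

#' Sobel mediation test with covariates
#'
#' Path model `x -> m -> y` with a freely estimated direct path `x -> y`
#' and shared covariates in both equations: `alpha` is the coefficient of
#' `x` in the regression of the mediator `m` on `x` plus covariates; `beta`
#' (mediator) and `tau_prime` (direct effect) come from the regression of
#' `y` on `x`, `m`, and covariates. The Sobel statistic is
#' `z = alpha*beta / sqrt(beta^2 se_alpha^2 + alpha^2 se_beta^2)` (classic
#' second-order formula) with a normal-approximation p-value; the full
#' mediation test is the t-test of `tau_prime = 0`. The total effect `tau`
#' (from `y` on `x` plus covariates, same complete cases) satisfies
#' `tau = tau_prime + alpha*beta` exactly under OLS.
#'
#' @param x Exposure (e.g. parental EA).
#' @param m Mediator (e.g. parental birthplace distance).
#' @param y Outcome (e.g. offspring F_roh).
#' @param covariates Optional data frame of covariates.
#' @return List (`mediation_result`): `alpha`, `se_alpha`, `beta`,
#'   `se_beta`, `tau_prime`, `tau_prime_p`, `tau`, `sobel_z`, `sobel_p`,
#'   `indirect` (= alpha*beta), `n`.
#' @export
sobel_test <- function(x, m, y, covariates = NULL) {
  dat <- data.frame(x = x, m = m, y = y)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (stats::sd(dat$m) == 0)
    stop("zero-variance mediator", call. = FALSE)
  covs <- dat[, setdiff(names(dat), c("x", "m", "y")), drop = FALSE]

  f_m <- ols(dat$m, cbind(data.frame(x = dat$x), covs))
  f_y <- ols(dat$y, cbind(data.frame(x = dat$x, m = dat$m), covs))
  f_t <- ols(dat$y, cbind(data.frame(x = dat$x), covs))

  alpha <- unname(f_m$beta["x"]); se_a <- unname(f_m$se["x"])
  beta <- unname(f_y$beta["m"]);  se_b <- unname(f_y$se["m"])
  tau_p <- unname(f_y$beta["x"])
  tau <- unname(f_t$beta["x"])
  se_sobel <- sqrt(beta^2 * se_a^2 + alpha^2 * se_b^2)
  z <- if (se_sobel > 0) alpha * beta / se_sobel else 0
  structure(list(
    alpha = alpha, se_alpha = se_a, beta = beta, se_beta = se_b,
    tau_prime = tau_p, tau_prime_p = unname(f_y$p["x"]),
    tau = tau, indirect = alpha * beta,
    sobel_z = z, sobel_p = 2 * stats::pnorm(-abs(z)),
    n = nrow(dat)
  ), class = "mediation_result")
}

#' Simulate a mediation cohort from the structural equations
#'
#' Generates `(x, m, y)` plus nuisance covariates directly from the linear
#' path model `m = alpha*x + e_m`, `y = tau_prime*x + beta*m + gamma'C +
#' e_y`, with `x` an ordinal EA level drawn from the study marginals and
#' standardized. Path coefficients are on the standardized scale (`sd(e)`
#' chosen so the marginal variances stay near 1). Used to test the mediation
#' statistics against controlled truth: `tau_prime = 0` gives pure
#' mediation, `alpha = beta = 0` with `tau_prime != 0` a direct-only effect.
#'
#' @param n Sample size.
#' @param alpha,beta,tau_prime Standardized path coefficients.
#' @param seed Integer seed.
#' @return Data frame `x`, `m`, `y`, `pc1`, `pc2`, `pc3`, `religion`,
#'   `city`.
#' @export
simulate_mediation_data <- function(n, alpha = 0.15, beta = 0.15,
                                    tau_prime = 0, seed = 1L) {
  set.seed(seed)
  ea <- sample(1:4, n, replace = TRUE, prob = ea_marginals_default("father"))
  x <- as.numeric(scale(ea))
  pc1 <- stats::rnorm(n); pc2 <- stats::rnorm(n); pc3 <- stats::rnorm(n)
  religion <- stats::rbinom(n, 1, 0.5)
  city <- stats::rbinom(n, 1, 0.5)
  m <- alpha * x + stats::rnorm(n, 0, sqrt(max(1 - alpha^2, 0.1)))
  y <- tau_prime * x + beta * m + 0.1 * pc1 + 0.05 * religion +
    stats::rnorm(n, 0, 1)
  data.frame(x = x, m = m, y = y, pc1 = pc1, pc2 = pc2, pc3 = pc3,
             religion = religion, city = city)
}
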