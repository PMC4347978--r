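# Gaussian-copula machinery for ordinal assortment.
#
# Two ordinal traits with given marginals are modelled as thresholded
# standard bivariate normals. The latent correlation needed to hit a target
# Spearman rho (computed on the discretized variables, midranks for ties)
# is found by 1-D root finding on the exact cell probabilities.

# P(Z1 <= a, Z2 <= b) for standard bivariate normal with correlation r,
# by integrating the conditional CDF over the first margin.
bvn_cdf <- function(a, b, r) {
  if (!is.finite(a) && a < 0) return(0)
  if (!is.finite(b) && b < 0) return(0)
  if (!is.finite(a) && !is.finite(b)) return(1)
  if (!is.finite(a)) return(stats::pnorm(b))
  if (!is.finite(b)) return(stats::pnorm(a))
  if (abs(r) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  s <- sqrt(1 - r^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((b - r * z) / s)
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# 4x4 (or r x c) cell probabilities for thresholded bivariate normal
copula_cell_probs <- function(r, marg_x, marg_y) {
  tx <- c(-Inf, stats::qnorm(cumsum(marg_x)[-length(marg_x)]), Inf)
  ty <- c(-Inf, stats::qnorm(cumsum(marg_y)[-length(marg_y)]), Inf)
  kx <- length(marg_x); ky <- length(marg_y)
  Fm <- matrix(0, kx + 1, ky + 1)
  for (i in 0:kx) for (j in 0:ky)
    Fm[i + 1, j + 1] <- bvn_cdf(tx[i + 1], ty[j + 1], r)
  P <- Fm[-1, -1] - Fm[-(kx + 1), -1] - Fm[-1, -(ky + 1)] +
    Fm[-(kx + 1), -(ky + 1)]
  pmax(P, 0)
}

# Spearman rho of a discrete joint distribution: Pearson correlation of the
# midrank scores (population version; ties handled by midranks).
spearman_from_probs <- function(P) {
  px <- rowSums(P); py <- colSums(P)
  ux <- cumsum(px) - px / 2     # midrank proportion per level
  uy <- cumsum(py) - py / 2
  mx <- sum(px * ux); my <- sum(py * uy)
  vx <- sum(px * (ux - mx)^2); vy <- sum(py * (uy - my)^2)
  cv <- sum(P * outer(ux - mx, uy - my))
  cv / sqrt(vx * vy)
}

# Latent normal correlation achieving a target discretized Spearman rho.
copula_latent_rho <- function(target_rho, marg_x, marg_y) {
  if (abs(target_rho) < 1e-12) return(0)
  if (abs(target_rho) >= 1)
    stop("unreachable assortment target: |rho| must be < 1", call. = FALSE)
  f <- function(r) spearman_from_probs(copula_cell_probs(r, marg_x, marg_y)) -
    target_rho
  # discretized Spearman is monotone in the latent r and bounded away from
  # +/-1; reject targets beyond the attainable range
  hi <- f(0.9999)
  if ((target_rho > 0 && hi < 0) || (target_rho < 0 && f(-0.9999) > 0))
    stop("unreachable assortment target for these marginals", call. = FALSE)
  stats::uniroot(f, c(-0.9999, 0.9999), tol = 1e-7)$root
}
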