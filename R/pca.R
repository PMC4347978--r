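# Ancestry principal components from standardized genotypes.

#' Principal components of a standardized genotype matrix
#'
#' Classic ancestry PCA: missing calls are mean-imputed per SNP, monomorphic
#' SNPs dropped, each SNP centered by twice its allele frequency estimate
#' `2*p` and scaled by `sqrt(2*p*(1-p))` (the binomial SD of a diploid
#' dosage), and the top `k` eigenvectors of the sample-by-sample covariance
#' extracted by exact eigendecomposition. Scores are eigenvector columns
#' scaled by the singular values, so they have zero mean, are mutually
#' orthogonal, and their variances are proportional to the eigenvalues.
#'
#' Component signs are arbitrary; downstream geography correlations should
#' compare absolute values or fix signs externally.
#'
#' @param G A [genotype_matrix()].
#' @param k Number of components (must be `<= min(n - 1, #SNPs)`).
#' @return List (`pc_scores`): `scores` (n x k), `eigenvalues` (length k),
#'   `loadings` (SNPs x k, on the standardized scale), `dropped_snps`.
#' @export
standardized_pca <- function(G, k = 3) {
  X <- G$calls
  n <- nrow(X)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    X[idx] <- mu[(idx - 1) %/% n + 1]
  }
  p_hat <- colMeans(X) / 2
  poly <- p_hat > 0 & p_hat < 1
  n_dropped <- sum(!poly)
  if (n_dropped) message(n_dropped, " monomorphic SNP(s) dropped before PCA")
  X <- X[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  m <- ncol(X)
  if (k > min(n - 1, m))
    stop("k exceeds min(n - 1, number of SNPs)", call. = FALSE)
  S <- sweep(X, 2, 2 * p_hat)
  S <- sweep(S, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  # row-center so scores are exactly mean-zero even with imputation noise
  S <- S - matrix(colMeans(S), n, m, byrow = TRUE)
  K <- tcrossprod(S)
  eg <- eigen(K, symmetric = TRUE)
  val <- pmax(eg$values[seq_len(k)], 0)
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  scores <- sweep(vec, 2, sqrt(val), "*")
  loadings <- crossprod(S, vec)
  loadings <- sweep(loadings, 2, pmax(sqrt(val), .Machine$double.eps), "/")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(G$calls)
  structure(list(scores = scores,
                 eigenvalues = val / (n - 1),
                 loadings = loadings,
                 dropped_snps = n_dropped),
            class = "pc_scores")
}

#' Pearson correlation between a PC and a geographic coordinate
#'
#' @param pc Component score vector.
#' @param coordinate Latitude or longitude vector (degrees).
#' @return Pearson correlation on complete cases.
#' @export
corr_pc_geo <- function(pc, coordinate) {
  ok <- stats::complete.cases(pc, coordinate)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(pc[ok]) == 0 || stats::sd(coordinate[ok]) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  stats::cor(pc[ok], coordinate[ok])
}
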