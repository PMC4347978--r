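# Independent oracles and small fixture builders shared across tests.

# Brute-force ROH scan: walk the call vector position by position, extending
# each maximal homozygous run by hand. Independent of the rle-based caller.
bf_rohs <- function(g, chrom, pos, min_snps, missing_breaks = TRUE) {
  valid <- if (missing_breaks) !is.na(g) & (g == 0 | g == 2)
           else is.na(g) | g == 0 | g == 2
  n <- length(g)
  out <- list()
  s <- 1
  while (s <= n) {
    if (!valid[s]) { s <- s + 1; next }
    e <- s
    while (e + 1 <= n && valid[e + 1] && chrom[e + 1] == chrom[s]) e <- e + 1
    if (e - s + 1 >= min_snps)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom[s], start_bp = pos[s], end_bp = pos[e],
        n_snps = e - s + 1L, length_bp = pos[e] - pos[s])
    s <- e + 1
  }
  if (!length(out))
    return(data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      length_bp = numeric()))
  do.call(rbind, out)
}

# one-sample genotype_matrix from a call vector on a single chromosome
gm1 <- function(g, chrom = rep(1L, length(g)), pos = seq_along(g) * 1000) {
  map <- data.frame(chrom = chrom, id = paste0("s", seq_along(g)),
                    pos = pos, a1 = "A", a2 = "C")
  genotype_matrix(matrix(as.integer(g), nrow = 1,
                         dimnames = list("ind1", NULL)), map)
}

# genotype vector generator with sticky homozygous stretches, so that runs
# near the 65-SNP threshold actually occur
random_sticky_calls <- function(n, p_switch = 0.02, p_missing = 0.01) {
  hom_state <- logical(n)
  hom_state[1] <- runif(1) < 0.5
  for (i in 2:n)
    hom_state[i] <- if (runif(1) < p_switch) !hom_state[i - 1]
                    else hom_state[i - 1]
  g <- ifelse(hom_state, sample(c(0L, 2L), n, replace = TRUE), 1L)
  g[runif(n) < p_missing] <- NA_integer_
  g
}

# direct VIF computation by explicit regression of each column on the rest
vif_direct <- function(Z) {
  vapply(seq_len(ncol(Z)), function(j) {
    fit <- stats::lm.fit(cbind(1, Z[, -j, drop = FALSE]), Z[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((Z[, j] - mean(Z[, j]))^2)
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
}

default_deme_map <- function() build_deme_map(10, 10, 15, origin = c(51.0, 4.5))
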