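# VIF pruning, ROH run calling, F_roh.

test_that("the 65-SNP boundary is respected", {
  g65 <- rep(2L, 65)
  segs <- call_rohs(gm1(g65), min_snps = 65)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 65L)
  expect_equal(segs$length_bp, 64 * 1000)

  g64 <- rep(2L, 64)
  expect_equal(nrow(call_rohs(gm1(g64), min_snps = 65)), 0)
})

test_that("a single heterozygote splits a long run", {
  g <- rep(0L, 130); g[66] <- 1L
  segs <- call_rohs(gm1(g), min_snps = 65)
  # left flank has 65 SNPs, right flank only 64
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 65L)
  expect_equal(segs$start_bp, 1000)
  expect_equal(segs$end_bp, 65000)
})

test_that("heterozygous and empty inputs give no segments", {
  expect_equal(nrow(call_rohs(gm1(rep(1L, 200)))), 0)
  dm <- default_deme_map()
  fam <- simulate_families(3, seed = 1, deme_map = dm)
  sim <- simulate_genotypes(fam, build_snp_map(1, 10, 1e6),
                            kinship_kernel = c(0, 50), seed = 2)
  expect_s3_class(call_rohs(sim$genotypes), "data.frame")
})

test_that("missing calls break runs by default but can be tolerated", {
  g <- rep(2L, 130); g[66] <- NA
  expect_equal(nrow(call_rohs(gm1(g), min_snps = 65)), 1) # left flank only
  segs <- call_rohs(gm1(g), min_snps = 65, missing_breaks = FALSE)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 130L)
})

test_that("runs never span chromosomes", {
  g <- rep(2L, 130)
  chrom <- rep(c(1L, 2L), each = 65)
  pos <- c(1:65 * 1000, 1:65 * 1000)
  segs <- call_rohs(gm1(g, chrom, pos), min_snps = 65)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$chrom, c(1L, 2L))
})

test_that("caller agrees with the brute-force scan oracle", {
  set.seed(101)
  for (trial in 1:200) {
    g <- random_sticky_calls(200)
    chrom <- rep(1:2, each = 100)
    pos <- c(sort(sample(1e6, 100)), sort(sample(1e6, 100)))
    min_snps <- sample(c(5, 20, 65), 1)
    got <- call_rohs(gm1(g, chrom, pos), min_snps = min_snps)
    want <- bf_rohs(g, chrom, pos, min_snps)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("calling is invariant to allele relabeling", {
  set.seed(102)
  g <- random_sticky_calls(300)
  flipped <- 2L - g
  expect_equal(call_rohs(gm1(g), min_snps = 30),
               call_rohs(gm1(flipped), min_snps = 30))
})

test_that("duplicated SNP columns lose exactly one of the pair", {
  set.seed(103)
  n <- 200
  X <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  X[, 6] <- X[, 5]                       # perfect duplicate inside a window
  map <- data.frame(chrom = 1L, id = paste0("s", 1:10), pos = 1:10 * 1000,
                    a1 = "A", a2 = "C")
  kept <- vif_prune(genotype_matrix(X, map), window_snps = 10, step_snps = 5)
  expect_equal(sum(c(5, 6) %in% kept), 1)
  expect_true(all(setdiff(1:10, c(5, 6)) %in% kept))
})

test_that("mutually uncorrelated SNPs survive pruning", {
  set.seed(104)
  n <- 500; m <- 300
  X <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]), n, m)
  map <- data.frame(chrom = 1L, id = paste0("s", 1:m), pos = 1:m * 1000,
                    a1 = "A", a2 = "C")
  kept <- vif_prune(genotype_matrix(X, map))
  expect_gte(length(kept), 0.95 * m)
})

test_that("pruning matches a direct VIF regression oracle on one window", {
  # 3 SNPs where SNP2 is SNP1 plus noise at r^2 ~ 0.6: VIF = 1/(1-0.6) = 2.5
  # exceeds the threshold, so the max-VIF SNP of the correlated pair goes
  set.seed(105)
  n <- 4000
  s1 <- rnorm(n)
  s2 <- sqrt(0.6) * s1 + sqrt(0.4) * rnorm(n)
  s3 <- rnorm(n)
  to_geno <- function(z) as.integer(cut(z, qnorm(c(0, .25, .75, 1)))) - 1L
  X <- cbind(to_geno(s1), to_geno(s2), to_geno(s3))
  Z <- scale(X)
  vifs <- vif_direct(Z)
  map <- data.frame(chrom = 1L, id = paste0("s", 1:3), pos = 1:3 * 1000,
                    a1 = "A", a2 = "C")
  kept <- vif_prune(genotype_matrix(X, map), window_snps = 3, step_snps = 1,
                    vif_threshold = 2)
  if (max(vifs) >= 2) {
    expect_equal(setdiff(1:3, kept), which.max(vifs))
  } else {
    expect_equal(kept, 1:3)
  }
})

test_that("pruning is deterministic and drops monomorphic SNPs first", {
  set.seed(106)
  X <- matrix(rbinom(100 * 20, 2, 0.5), 100, 20)
  X[, 7] <- 2L
  map <- data.frame(chrom = 1L, id = paste0("s", 1:20), pos = 1:20 * 1000,
                    a1 = "A", a2 = "C")
  G <- genotype_matrix(X, map)
  expect_message(k1 <- vif_prune(G, 10, 5), "monomorphic")
  k2 <- suppressMessages(vif_prune(G, 10, 5))
  expect_identical(k1, k2)
  expect_false(7 %in% k1)
})

test_that("F_roh arithmetic and guards", {
  empty <- call_rohs(gm1(rep(1L, 100)))
  fr <- compute_froh(empty, 2.77e9, sample_ids = "ind1")
  expect_equal(fr$froh, 0)

  seg <- data.frame(sample_id = "a", chrom = 1L, start_bp = 1,
                    end_bp = 27700001, n_snps = 100,
                    length_bp = 27700000)
  expect_equal(compute_froh(seg, 2.77e9)$froh, 0.01)

  overlap <- rbind(seg, data.frame(sample_id = "a", chrom = 1L,
                                   start_bp = 27000000, end_bp = 28000000,
                                   n_snps = 70, length_bp = 1000000))
  expect_error(compute_froh(overlap, 2.77e9), "overlap")
  expect_error(compute_froh(seg, 0), "denominator_bp > 0")
})

test_that("F_roh tracks the true HBD fraction in a simulated cohort", {
  dm <- default_deme_map()
  fam <- simulate_families(300, seed = 31, deme_map = dm)
  sim <- simulate_genotypes(fam, build_snp_map(), seed = 32, deme_map = dm)
  segs <- call_rohs(sim$genotypes)
  fr <- compute_froh(segs, mappable_length(sim$genotypes$map),
                     rownames(sim$genotypes$calls))
  truth <- hbd_fraction(sim$truth)[fr$sample_id]
  expect_gt(cor(fr$froh, truth, method = "spearman"), 0.9)
})
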