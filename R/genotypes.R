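# Genotype container, SNP map builder, and the genotype simulator: spatial
# allele-frequency clines plus homozygosity-by-descent (HBD) tracts whose
# genome-wide expectation is half the parental kinship.

#' Construct a genotype matrix object
#'
#' @param calls Integer matrix, samples x SNPs, values in `{0, 1, 2, NA}`
#'   (counted-allele dosage; `NA` = missing call). Row names are sample ids.
#' @param map Data frame with one row per SNP: `chrom`, `id`, `pos`
#'   (1-based bp), `a1`, `a2`. Positions must be strictly increasing within
#'   chromosome.
#' @return A `genotype_matrix` (list with `calls`, `map`, `sample_ids`).
#' @export
genotype_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  if (ncol(calls) != nrow(map))
    stop("ncol(calls) must equal nrow(map)", call. = FALSE)
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome",
           call. = FALSE)
  }
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  structure(list(calls = calls, map = map, sample_ids = rownames(calls)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  invisible(x)
}

#' Build an evenly spaced SNP map
#'
#' Default genome for desk-scale simulation: 5 chromosomes of 30 Mb with
#' 2,000 evenly spaced SNPs each (15 kb spacing), roughly the marker density
#' of an LD-pruned genotyping array, dense enough that 65-SNP runs of
#' homozygosity span about 1 Mb.
#'
#' @param n_chr Number of chromosomes.
#' @param snps_per_chr SNPs per chromosome.
#' @param chr_length_bp Chromosome length in bases.
#' @return SNP map data frame (`chrom`, `id`, `pos`, `a1`, `a2`).
#' @export
build_snp_map <- function(n_chr = 5, snps_per_chr = 2000,
                          chr_length_bp = 30e6) {
  spacing <- chr_length_bp / snps_per_chr
  pos <- round(spacing * seq_len(snps_per_chr))
  do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    data.frame(chrom = ch,
               id = sprintf("snp%d_%d", ch, seq_len(snps_per_chr)),
               pos = pos, a1 = "A", a2 = "C")
  }))
}

#' Simulate genotypes with spatial structure and distance-dependent HBD
#'
#' Population structure: each SNP gets a baseline logit frequency (uniform
#' 0.1-0.9 on the probability scale) and per-axis logit gradients drawn as
#' `N(0, cline_strength^2)` per degree of latitude/longitude, so latitude
#' explains more frequency variance than longitude when
#' `cline_strength[1] > cline_strength[2]` (distinct north-south and
#' east-west ancestry axes). Deme frequencies are then drawn from a finite
#' haplotype pool of `pool_size` diploids (binomial drift around the cline).
#'
#' Autozygosity: parents at birthplace distance `d` km have kinship
#' `phi = phi0 * exp(-d / lambda_km)`; their offspring's genome alternates
#' between HBD and non-HBD states as a two-state Markov process along each
#' chromosome with stationary HBD fraction `phi / 2` and mean HBD tract
#' length `mean_hbd_tract_morgan` (mapped to bp at `cm_per_mb` cM/Mb).
#' Outside HBD tracts the two alleles are drawn independently at the
#' father's and the mother's origin-deme frequencies (each parent maps to
#' the deme nearest their birthplace), so an offspring's ancestry reflects
#' the parental origins rather than their own birthplace — the mechanism by
#' which education-dependent parental migration weakens the correlation
#' between offspring ancestry and offspring birthplace. Inside HBD tracts a
#' single allele is drawn at the mean parental frequency and doubled, so
#' every call in the tract is homozygous.
#'
#' @param families Family table from [simulate_families()].
#' @param snp_map SNP map from [build_snp_map()].
#' @param kinship_kernel Numeric `(phi0, lambda_km)`: kinship at distance 0
#'   (in `[0, 1]`) and decay length in km.
#' @param cline_strength Per-axis SD of per-SNP logit gradients, per degree,
#'   `(latitude, longitude)`.
#' @param pool_size Deme haplotype-pool size (diploids); larger = less drift.
#' @param seed Integer seed.
#' @param deme_map Optional deme grid; defaults to demes inferred from the
#'   offspring coordinates in `families`.
#' @param mean_hbd_tract_morgan Mean HBD tract length in Morgans.
#' @param cm_per_mb Genetic map density (centimorgan per megabase).
#' @param missing_rate Fraction of calls set missing at random.
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth` (a
#'   `simulation_truth`: HBD `segments` data frame with `sample_id`,
#'   `chrom`, `start`, `end`; per-family `phi`; generator `params`).
#' @export
simulate_genotypes <- function(families,
                               snp_map = build_snp_map(),
                               kinship_kernel = c(phi0 = 0.0625, lambda_km = 50),
                               cline_strength = c(0.8, 0.4),
                               pool_size = 100,
                               seed = 1L,
                               deme_map = NULL,
                               mean_hbd_tract_morgan = 0.1,
                               cm_per_mb = 1,
                               missing_rate = 0) {
  if (nrow(snp_map) == 0) stop("empty SNP map", call. = FALSE)
  phi0 <- kinship_kernel[[1]]; lambda <- kinship_kernel[[2]]
  if (phi0 < 0 || phi0 > 1) stop("phi0 must be in [0, 1]", call. = FALSE)
  if (lambda <= 0) stop("lambda_km must be positive", call. = FALSE)
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("snp_map must be sorted by (chromosome, position)", call. = FALSE)
  }
  set.seed(seed)

  n <- nrow(families)
  m <- nrow(snp_map)
  chroms <- unique(snp_map$chrom)
  chr_len <- vapply(chroms, function(ch) max(snp_map$pos[snp_map$chrom == ch]),
                    numeric(1))
  names(chr_len) <- chroms

  # deme coordinates; each family member maps to their nearest deme
  if (is.null(deme_map)) {
    key <- paste(families$o_lat, families$o_lon)
    ud <- !duplicated(key)
    deme_lat <- families$o_lat[ud]; deme_lon <- families$o_lon[ud]
  } else {
    deme_lat <- deme_map$lat; deme_lon <- deme_map$lon
  }
  n_demes <- length(deme_lat)
  w_lon <- cos(mean(range(deme_lat)) * pi / 180)^2
  nearest_ix <- function(lat, lon) {
    vapply(seq_along(lat), function(i) {
      which.min((deme_lat - lat[i])^2 + w_lon * (deme_lon - lon[i])^2)
    }, integer(1))
  }
  f_deme <- nearest_ix(families$f_lat, families$f_lon)
  m_deme <- nearest_ix(families$m_lat, families$m_lon)

  # allele-frequency field: cline + pool drift
  base_logit <- stats::qlogis(stats::runif(m, 0.1, 0.9))
  s_lat <- stats::rnorm(m, 0, cline_strength[1])
  s_lon <- stats::rnorm(m, 0, cline_strength[2])
  lat_c <- deme_lat - mean(deme_lat)
  lon_c <- deme_lon - mean(deme_lon)
  # demes x SNPs cline frequencies
  P <- stats::plogis(matrix(base_logit, n_demes, m, byrow = TRUE) +
                       outer(lat_c, s_lat) + outer(lon_c, s_lon))
  haps <- 2L * pool_size
  P <- matrix(stats::rbinom(n_demes * m, haps, P) / haps, n_demes, m)

  # parental kinship and HBD tract process
  d_par <- great_circle_km(families$f_lat, families$f_lon,
                           families$m_lat, families$m_lon)
  phi <- phi0 * exp(-d_par / lambda)
  bp_per_morgan <- 1e8 / cm_per_mb
  mean_hbd_bp <- mean_hbd_tract_morgan * bp_per_morgan

  sample_ids <- paste0("fam", families$family_id)
  seg_list <- vector("list", n)
  for (i in seq_len(n)) {
    pi_i <- phi[i] / 2
    if (pi_i <= 0) next
    mean_out_bp <- mean_hbd_bp * (1 - pi_i) / pi_i
    segs <- list()
    for (ch in chroms) {
      L <- chr_len[[as.character(ch)]]
      pos <- 0
      state <- stats::runif(1) < pi_i
      while (pos < L) {
        len <- stats::rexp(1, 1 / if (state) mean_hbd_bp else mean_out_bp)
        end <- min(pos + len, L)
        if (state && end > pos)
          segs[[length(segs) + 1]] <-
            c(chrom = ch, start = floor(pos) + 1, end = floor(end))
        pos <- end
        state <- !state
      }
    }
    if (length(segs))
      seg_list[[i]] <- data.frame(
        sample_id = sample_ids[i],
        chrom = vapply(segs, `[[`, numeric(1), "chrom"),
        start = vapply(segs, `[[`, numeric(1), "start"),
        end = vapply(segs, `[[`, numeric(1), "end")
      )
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments))
    segments <- data.frame(sample_id = character(), chrom = numeric(),
                           start = numeric(), end = numeric())
  segments <- segments[segments$end >= segments$start, , drop = FALSE]

  # genotype calls: one allele drawn at the father's origin-deme frequency,
  # one at the mother's, so offspring ancestry reflects the parental
  # origins, not the offspring's own birthplace; inside HBD tracts a single
  # allele is drawn at the mean parental frequency and doubled
  chrom_col <- snp_map$chrom
  pos_col <- snp_map$pos
  calls <- matrix(NA_integer_, n, m)
  for (i in seq_len(n)) {
    p_f <- P[f_deme[i], ]
    p_m <- P[m_deme[i], ]
    g <- stats::rbinom(m, 1L, p_f) + stats::rbinom(m, 1L, p_m)
    if (nrow(segments)) {
      si <- segments[segments$sample_id == sample_ids[i], , drop = FALSE]
      if (nrow(si)) {
        hbd <- rep(FALSE, m)
        for (k in seq_len(nrow(si)))
          hbd <- hbd | (chrom_col == si$chrom[k] &
                          pos_col >= si$start[k] & pos_col <= si$end[k])
        nh <- sum(hbd)
        if (nh) g[hbd] <- 2L * stats::rbinom(nh, 1L,
                                             (p_f[hbd] + p_m[hbd]) / 2)
      }
    }
    calls[i, ] <- g
  }
  if (missing_rate > 0) {
    drop <- stats::runif(n * m) < missing_rate
    calls[drop] <- NA_integer_
  }
  rownames(calls) <- sample_ids

  truth <- structure(list(
    segments = segments,
    phi = stats::setNames(phi, sample_ids),
    params = list(phi0 = phi0, lambda_km = lambda,
                  cline_strength = cline_strength, pool_size = pool_size,
                  mean_hbd_tract_morgan = mean_hbd_tract_morgan,
                  cm_per_mb = cm_per_mb, chr_len = chr_len,
                  genome_bp = sum(chr_len))
  ), class = "simulation_truth")

  list(genotypes = genotype_matrix(calls, snp_map), truth = truth)
}

#' True HBD genome fraction per sample
#'
#' Total truth HBD length divided by the simulated genome length, for every
#' sample in `sample_ids` (zero when a sample carries no HBD tract).
#'
#' @param truth `simulation_truth` from [simulate_genotypes()].
#' @param sample_ids Samples to report; defaults to all samples in `truth`.
#' @return Named numeric vector of HBD fractions.
#' @export
hbd_fraction <- function(truth, sample_ids = names(truth$phi)) {
  segs <- truth$segments
  len <- tapply(segs$end - segs$start + 1, segs$sample_id, sum)
  out <- stats::setNames(numeric(length(sample_ids)), sample_ids)
  hit <- intersect(names(len), sample_ids)
  out[hit] <- len[hit] / truth$params$genome_bp
  out
}
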