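# LD pruning by variance inflation factor, run-of-homozygosity calling, and
# the F_roh autozygosity statistic.

#' Prune SNPs by variance inflation factor
#'
#' Sliding-window VIF pruning in the style of array LD thinning: within each
#' window of `window_snps` currently kept SNPs (per chromosome), each SNP's
#' VIF `1 / (1 - R^2)` is computed from the regression of its standardized
#' genotype on the other kept SNPs in the window; the SNP with the largest
#' VIF is removed (ties broken by removing the lower minor-allele-frequency
#' SNP) until all VIFs are below `vif_threshold`, and the window advances by
#' `step_snps`. VIFs are read off the diagonal of the inverse correlation
#' matrix, with a tiny ridge so that perfectly collinear SNPs yield huge
#' (finite) VIFs and deterministic removal.
#'
#' Monomorphic SNPs (zero variance after mean-imputing missing calls) are
#' dropped before pruning; their count is reported via `message()`.
#'
#' @param G A [genotype_matrix()].
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps SNPs to shift the window after each step (default 5).
#' @param vif_threshold VIF above which a SNP is removed (default 2).
#' @return Integer vector of kept SNP column indices, in input order.
#' @export
vif_prune <- function(G, window_snps = 50, step_snps = 5, vif_threshold = 2) {
  stopifnot(window_snps > step_snps, step_snps > 0, vif_threshold > 1)
  X <- G$calls
  m <- ncol(X)
  # mean-impute missing calls for the correlation computations
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    X[idx] <- mu[(idx - 1) %/% nrow(X) + 1]
  }
  v <- apply(X, 2, stats::var)
  mono <- v == 0 | is.na(v)
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s) dropped before pruning")
  maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)

  keep <- !mono
  Z <- scale(X)
  for (ch in unique(G$map$chrom)) {
    cols <- which(G$map$chrom == ch)
    start <- 1
    while (start <= length(cols)) {
      win_all <- cols[start:min(start + window_snps - 1, length(cols))]
      win <- win_all[keep[win_all]]
      while (length(win) > 1) {
        C <- crossprod(Z[, win, drop = FALSE]) / (nrow(Z) - 1)
        diag(C) <- diag(C) + 1e-10
        Cinv <- tryCatch(solve(C), error = function(e) NULL)
        if (is.null(Cinv)) { # numerically singular even with ridge
          vifs <- rep(Inf, length(win))
        } else {
          vifs <- diag(Cinv)
        }
        if (max(vifs) < vif_threshold) break
        worst <- which(vifs == max(vifs))
        if (length(worst) > 1) # tie: drop the lower-MAF SNP
          worst <- worst[which.min(maf[win[worst]])]
        else worst <- worst[1]
        keep[win[worst]] <- FALSE
        win <- win[-worst]
      }
      if (start + window_snps - 1 >= length(cols)) break
      start <- start + step_snps
    }
  }
  which(keep)
}

#' Subset a genotype matrix to a set of SNP columns
#'
#' @param G A [genotype_matrix()].
#' @param snp_idx Column indices to keep (e.g. from [vif_prune()]).
#' @return A new `genotype_matrix`.
#' @export
subset_snps <- function(G, snp_idx) {
  genotype_matrix(G$calls[, snp_idx, drop = FALSE],
                  G$map[snp_idx, , drop = FALSE])
}

#' Call runs of homozygosity
#'
#' Per sample and chromosome, finds maximal runs of consecutive analyzed
#' SNPs whose calls are homozygous (`0` or `2`); a heterozygous call always
#' terminates a run, and a missing call terminates it too when
#' `missing_breaks = TRUE` (the default, conservative reading; with
#' `missing_breaks = FALSE` missing calls are tolerated inside a run and
#' counted in its SNP span). Runs with at least `min_snps` SNPs are emitted.
#' Runs never span chromosomes. Segment length follows the kb convention
#' `end_bp - start_bp` of the standard ROH tooling (not `+ 1`).
#'
#' @param G A [genotype_matrix()] (normally after LD pruning).
#' @param min_snps Minimum number of consecutive homozygous SNPs (default 65).
#' @param missing_breaks Whether a missing call terminates a run.
#' @return Data frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`.
#' @export
call_rohs <- function(G, min_snps = 65, missing_breaks = TRUE) {
  calls <- G$calls
  map <- G$map
  # chromosome change points induce forced breaks
  chrom <- map$chrom
  new_chr <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  res <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- calls[i, ]
    hom <- g == 0L | g == 2L
    if (missing_breaks) {
      hom[is.na(hom)] <- FALSE
    } else {
      hom[is.na(hom)] <- TRUE   # tolerated, counted in span
    }
    # break runs at chromosome starts by interleaving sentinel FALSEs
    run_id <- cumsum(new_chr)
    r <- rle(paste0(hom, ".", run_id))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    is_hom_run <- startsWith(r$values, "TRUE")
    sel <- is_hom_run & r$lengths >= min_snps
    if (!any(sel)) next
    s <- starts[sel]; e <- ends[sel]
    res[[i]] <- data.frame(
      sample_id = rownames(calls)[i],
      chrom = chrom[s],
      start_bp = map$pos[s],
      end_bp = map$pos[e],
      n_snps = e - s + 1L,
      length_bp = map$pos[e] - map$pos[s]
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric())
  rownames(out) <- NULL
  out
}

#' Genome fraction in runs of homozygosity (F_roh)
#'
#' Sums each sample's segment lengths and divides by `denominator_bp`. On a
#' real genotyping array the denominator is the total SNP-mappable autosomal
#' distance, 2.77e9 bases; for simulated genomes use
#' [mappable_length()] of the SNP map.
#'
#' @param segments Segment data frame from [call_rohs()].
#' @param denominator_bp Total mappable autosomal length in bases.
#' @param sample_ids Samples to report (samples without segments get 0);
#'   defaults to the samples present in `segments`.
#' @return Data frame `sample_id`, `froh`, `denominator_bp`.
#' @export
compute_froh <- function(segments, denominator_bp = 2.77e9,
                         sample_ids = NULL) {
  stopifnot(denominator_bp > 0)
  if (nrow(segments)) {
    key <- paste(segments$sample_id, segments$chrom)
    for (k in unique(key)) {
      si <- segments[key == k, , drop = FALSE]
      si <- si[order(si$start_bp), , drop = FALSE]
      if (nrow(si) > 1 && any(si$start_bp[-1] <= si$end_bp[-nrow(si)]))
        stop("overlapping ROH segments for sample ",
             si$sample_id[1], " chromosome ", si$chrom[1], call. = FALSE)
    }
  }
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  tot <- tapply(segments$length_bp, segments$sample_id, sum)
  froh <- stats::setNames(numeric(length(sample_ids)), sample_ids)
  hit <- intersect(names(tot), sample_ids)
  froh[hit] <- tot[hit] / denominator_bp
  if (any(froh > 1)) stop("F_roh above 1: check denominator", call. = FALSE)
  data.frame(sample_id = sample_ids, froh = as.numeric(froh),
             denominator_bp = denominator_bp, row.names = NULL)
}

#' Total mapped length of a SNP map
#'
#' Sum over chromosomes of (last - first) mapped position: the natural
#' F_roh denominator for a simulated genome.
#'
#' @param snp_map SNP map data frame (`chrom`, `pos`).
#' @return Length in bases.
#' @export
mappable_length <- function(snp_map) {
  sum(tapply(snp_map$pos, snp_map$chrom, function(p) max(p) - min(p)))
}
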