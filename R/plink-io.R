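# PLINK 1 text (.ped/.map) and binary (.bed/.bim/.fam) genotype IO.
#
# Binary layout: 3 magic bytes 0x6c 0x1b, then 0x01 for SNP-major order;
# each SNP is packed 4 samples per byte, low bits first, with 2-bit codes
# 00 = homozygous A1A1 (dosage 2), 01 = missing, 10 = heterozygous,
# 11 = homozygous A2A2 (dosage 0). Calls are dosages of allele A1.

.bed_code <- c(`2` = 0L, `NA` = 1L, `1` = 2L, `0` = 3L)
.bed_decode <- c(2L, NA_integer_, 1L, 0L)  # index by code + 1

#' Write a genotype matrix as PLINK binary (.bed/.bim/.fam)
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(G, prefix) {
  calls <- G$calls; map <- G$map
  n <- nrow(calls); m <- ncol(calls)
  fam <- data.frame(fid = rownames(calls), iid = rownames(calls),
                    pid = 0, mid = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = map$chrom, id = map$id, cm = 0,
                    pos = format(map$pos, scientific = FALSE, trim = TRUE),
                    a1 = map$a1, a2 = map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  code <- matrix(3L, n, m)
  code[calls == 2L] <- 0L
  code[is.na(calls)] <- 1L
  code[calls == 1L] <- 2L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  # pack 4 codes per byte, first sample in the lowest 2 bits
  i1 <- seq(1, nrow(code), by = 4)
  packed <- code[i1, , drop = FALSE] +
    4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] +
    64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Validates the magic bytes and requires SNP-major order; truncated files
#' are rejected. Calls are decoded to A1-allele dosages `{0, 1, 2, NA}`.
#'
#' @param prefix Path prefix of the fileset.
#' @return A [genotype_matrix()].
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           colClasses = c("character", "character", "NULL",
                                          "NULL", "NULL", "NULL"))
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "numeric", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic number", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("sample-major .bed files are not supported", call. = FALSE)
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop("truncated .bed file: expected ", bytes_per_snp * m,
         " body bytes, found ", length(body), call. = FALSE)
  # 256 x 4 lookup: byte value -> 4 dosages
  byte_vals <- 0:255
  lut <- cbind(.bed_decode[byte_vals %% 4 + 1],
               .bed_decode[(byte_vals %/% 4) %% 4 + 1],
               .bed_decode[(byte_vals %/% 16) %% 4 + 1],
               .bed_decode[(byte_vals %/% 64) %% 4 + 1])
  dos <- lut[as.integer(body) + 1, , drop = FALSE]  # (bytes) x 4
  calls <- matrix(t(dos), ncol = m)[seq_len(n), , drop = FALSE]
  rownames(calls) <- fam[[2]]
  map <- bim[, c("chrom", "id", "pos", "a1", "a2")]
  genotype_matrix(calls, map)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Genotypes are written as allele pairs (`a1`/`a2` letters from the map;
#' `0 0` for missing).
#'
#' @inheritParams write_plink_bed
#' @export
write_plink_ped <- function(G, prefix) {
  calls <- G$calls; map <- G$map
  n <- nrow(calls)
  a1 <- map$a1; a2 <- map$a2
  lines <- vapply(seq_len(n), function(i) {
    g <- calls[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    paste(rownames(calls)[i], rownames(calls)[i], 0, 0, 0, -9,
          paste(al1, al2, collapse = " "))
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  mp <- data.frame(chrom = map$chrom, id = map$id, cm = 0,
                   pos = format(map$pos, scientific = FALSE, trim = TRUE))
  utils::write.table(mp, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Calls are dosages of each SNP's minor allele (the less frequent allele
#' among the observed calls; ties broken alphabetically), matching the
#' usual A1 = minor convention of the binary format.
#'
#' @param prefix Path prefix of the fileset.
#' @return A [genotype_matrix()].
#' @export
read_plink_ped <- function(prefix) {
  mp <- utils::read.table(paste0(prefix, ".map"),
                          col.names = c("chrom", "id", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(mp)
  if (ncol(ped) != 6 + 2 * m)
    stop(".ped column count does not match .map", call. = FALSE)
  ids <- ped[[2]]
  A1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  A2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    als <- c(A1[, j], A2[, j])
    obs <- als[als != "0"]
    lv <- sort(unique(obs))
    if (length(lv) == 0) { a1[j] <- "0"; a2[j] <- "0"; next }
    if (length(lv) == 1) lv <- c(lv, lv)
    cnt <- c(sum(obs == lv[1]), sum(obs == lv[2]))
    minor <- if (cnt[2] < cnt[1]) lv[2] else lv[1]  # tie -> alphabetical
    major <- setdiff(lv, minor)[1]
    if (is.na(major)) major <- minor
    a1[j] <- minor; a2[j] <- major
    miss <- A1[, j] == "0" | A2[, j] == "0"
    calls[, j] <- (A1[, j] == minor) + (A2[, j] == minor)
    calls[miss, j] <- NA_integer_
  }
  rownames(calls) <- ids
  map <- data.frame(chrom = mp$chrom, id = mp$id, pos = mp$pos,
                    a1 = a1, a2 = a2)
  genotype_matrix(calls, map)
}

#' Write a family covariate table as TSV
#'
#' Column layout: `family_id`, `father_ea`, `mother_ea`, `offspring_ea`,
#' `f_lat`, `f_lon`, `m_lat`, `m_lon`, `o_lat`, `o_lon`, `religion`, `city`
#' (plus any extra columns present).
#'
#' @param families Family table.
#' @param path Output file.
#' @export
write_covariates_tsv <- function(families, path) {
  utils::write.table(families, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Write truth HBD segments as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `sample`.
#'
#' @param truth `simulation_truth` from [simulate_genotypes()].
#' @param path Output file.
#' @export
write_truth_hbd <- function(truth, path) {
  segs <- truth$segments[, c("chrom", "start", "end", "sample_id")]
  names(segs)[4] <- "sample"
  utils::write.table(segs, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
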