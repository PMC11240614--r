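# PLINK 1 binary (bed/bim/fam) IO. The .bed payload is SNP-major, 2 bits per
# genotype, little-endian within a byte: 00 = two copies of A1, 10 = het,
# 11 = zero copies of A1, 01 = missing. The counted allele is A1 (bim col 5).

#' Read a PLINK bed/bim/fam triple
#'
#' @param prefix path prefix: `prefix.bed`, `prefix.bim`, `prefix.fam` must all
#'   exist. Sample order follows the fam file, SNP order the bim file.
#' @return A [genotype_matrix()] whose calls count copies of the A1 allele.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  }
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  bim_df <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bim_df) < 6) stop("malformed bim file: expected 6 columns")
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed files are supported: ", bed)
  }
  bytes_per_snp <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m) {
    stop("bed payload size (", length(payload), " bytes) inconsistent with ",
         n, " samples x ", m, " SNPs in fam/bim")
  }
  # decode 2-bit fields: for each byte, 4 genotypes, least significant pair first
  mat <- matrix(as.integer(payload), nrow = bytes_per_snp, ncol = m)
  lut <- c(2L, NA_integer_, 1L, 0L)  # bit pairs 00,01,10,11 -> A1 dosage
  calls <- matrix(NA_integer_, n, m)
  for (k in 0:3) {
    idx_sample <- seq.int(k + 1L, by = 4L, length.out = bytes_per_snp)
    idx_sample <- idx_sample[idx_sample <= n]
    if (length(idx_sample) == 0) next
    byte_rows <- ((idx_sample - 1L) %/% 4L) + 1L
    pair <- (mat[byte_rows, , drop = FALSE] %/% (4L^k)) %% 4L
    calls[idx_sample, ] <- lut[pair + 1L]
  }
  map <- data.frame(id = bim_df[[2]], chr = bim_df[[1]],
                    pos = as.integer(bim_df[[4]]),
                    a1 = bim_df[[5]], a2 = bim_df[[6]])
  genotype_matrix(calls, map = map, samples = fam_df[[2]])
}

#' Write a genotype matrix as a PLINK bed/bim/fam triple
#'
#' Inverse of [read_plink()]: the counted allele is written as A1 and
#' `read_plink(write_plink(g))` reproduces the calls exactly.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param pedigree optional data.frame with columns `id`, `sire`, `dam` used to
#'   fill the fam parental columns; unknown parents are written as 0.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, pedigree = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$calls)
  m <- ncol(g$calls)
  sire <- dam <- rep("0", n)
  if (!is.null(pedigree)) {
    i <- match(g$samples, pedigree$id)
    sire <- ifelse(is.na(i), "0", as.character(pedigree$sire[i]))
    dam <- ifelse(is.na(i), "0", as.character(pedigree$dam[i]))
  }
  fam <- data.frame(fid = g$samples, iid = g$samples, pat = sire, mat = dam,
                    sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = g$map$chr, id = g$map$id, cm = 0L, pos = g$map$pos,
                    a1 = g$map$a1, a2 = g$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bytes_per_snp <- ceiling(n / 4)
  code <- matrix(0L, 4L * bytes_per_snp, m)  # zero-bit padding, as plink writes
  enc <- c(0L, 2L, 3L)                       # dosage 2,1,0 handled via lookup below
  x <- g$calls
  coded <- ifelse(is.na(x), 1L, enc[3L - x]) # dosage 0->11(3), 1->10(2), 2->00(0)
  code[seq_len(n), ] <- coded
  # pack 4 fields per byte, least significant pair first
  i1 <- seq.int(1L, 4L * bytes_per_snp, by = 4L)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
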