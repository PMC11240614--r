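# VCF IO. Reading goes through vcfR; only the GT field is consumed and the ALT
# allele is the counted allele, so a VCF and a PLINK representation of the same
# panel (with A1 = ALT) decode to identical genotype matrices.

#' Read genotypes from a VCF file
#'
#' Biallelic records only: multiallelic ALT fields are skipped with a warning.
#' GT values `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./.` -> missing
#' (phased separators `|` are accepted); the ALT allele is the counted allele.
#'
#' @param path a VCF file (plain or bgzipped) with a GT FORMAT field.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  if (!"GT" %in% unlist(strsplit(v@gt[1, "FORMAT"], ":"))) {
    stop("VCF has no GT field: ", path)
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning("skipping ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt_clean <- gsub("\\|", "/", gt)
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- matrix(lut[gt_clean], nrow = nrow(gt_clean), ncol = ncol(gt_clean))
  unknown <- !is.na(gt_clean) & !(gt_clean %in% c(names(lut), "./.", "."))
  if (any(unknown)) {
    stop("unsupported GT value(s): ",
         paste(utils::head(unique(gt_clean[unknown])), collapse = ", "))
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(id = ids, chr = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    a1 = fix[, "ALT"], a2 = fix[, "REF"])
  genotype_matrix(t(calls), map = map, samples = colnames(gt))
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCFv4.2 with GT-only genotypes. The counted allele (`a1`)
#' is written as ALT and `a2` as REF, so [read_vcf()] round-trips the calls
#' exactly and agrees with the PLINK representation written by
#' [write_plink()].
#'
#' @param g a [genotype_matrix()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", ncol(g$calls), nrow(g$calls))
  idx <- !is.na(t(g$calls))
  body[idx] <- gt_str[t(g$calls)[idx] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=heterogen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"),
    paste(g$map$chr, g$map$pos, g$map$id, g$map$a2, g$map$a1, ".", ".", ".",
          "GT", apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
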