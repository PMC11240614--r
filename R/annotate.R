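#' Read gene intervals from a GFF3 annotation
#'
#' Thin wrapper over `rtracklayer::import()` keeping `gene` features and the
#' columns the nearest-gene annotation needs.
#'
#' @param path GFF3 file.
#' @param feature_type feature type(s) retained (default `"gene"`).
#' @return data.frame with columns `gene`, `chr`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_annotation() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  gene <- ifelse(is.na(nm) | nm == "", id, nm)
  data.frame(gene = gene,
             chr = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Annotate SNPs with their nearest gene
#'
#' For each SNP, the gene on the same chromosome with the smallest boundary
#' distance is reported. A SNP inside a gene gets distance 0. The sign
#' follows genomic-coordinate orientation: positive when the gene lies at
#' higher coordinates than the SNP (gene start beyond the SNP), negative when
#' the gene lies at lower coordinates (gene end before the SNP). Ties between
#' equidistant genes go to the gene with the smaller start coordinate, with a
#' message. Gene strand is carried along but does not affect the sign.
#'
#' @param snps data.frame with columns `id` (or `snp`), `chr`, `pos`.
#' @param genes data.frame with columns `gene`, `chr`, `start`, `end` (and
#'   optionally `strand`), e.g. from [read_gene_annotation()].
#' @return data.frame: `snp`, `chr`, `pos`, `gene`, `distance` (signed bp;
#'   `NA` with a warning for SNPs on chromosomes absent from the annotation),
#'   `strand`.
#' @export
annotate_nearest_gene <- function(snps, genes) {
  if (!is.null(snps$snp) && is.null(snps$id)) snps$id <- snps$snp
  stopifnot(all(c("id", "chr", "pos") %in% names(snps)),
            all(c("gene", "chr", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("gene intervals must have start <= end")
  if (is.null(genes$strand)) genes$strand <- "*"
  out <- data.frame(snp = snps$id, chr = as.character(snps$chr),
                    pos = snps$pos, gene = NA_character_,
                    distance = NA_real_, strand = NA_character_)
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chr == as.character(snps$chr[i]), , drop = FALSE]
    if (nrow(g) == 0) next
    pos <- snps$pos[i]
    inside <- pos >= g$start & pos <= g$end
    d <- ifelse(inside, 0,
                ifelse(pos < g$start, g$start - pos, -(pos - g$end)))
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1) {
      message("SNP ", snps$id[i], ": ", length(best),
              " equidistant genes; reporting the smaller start coordinate")
      best <- best[which.min(g$start[best])]
    }
    out$gene[i] <- g$gene[best]
    out$distance[i] <- d[best]
    out$strand[i] <- g$strand[best]
  }
  if (anyNA(out$gene)) {
    warning(sum(is.na(out$gene)),
            " SNP(s) on chromosomes absent from the annotation")
  }
  out
}
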