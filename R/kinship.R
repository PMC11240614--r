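# Genomic relationship matrices. Additive: VanRaden method 1,
# Ga = ZZ' / sum_j 2 p_j (1 - p_j). Dominance: heterozygosity coding,
# Gd = WW' / sum_j [2 p_j (1 - p_j)]^2. Both inherit their centering from
# build_designs(); the stored matrix is exactly the formula — any ridge needed
# for solving is added inside the solvers, never here.

.grm_new <- function(values, kind, samples, denominator) {
  dimnames(values) <- list(samples, samples)
  structure(list(values = values, kind = kind, samples = samples,
                 denominator = denominator),
            class = "grm")
}

#' Additive genomic relationship matrix
#'
#' @param designs a `design_pair` from [build_designs()].
#' @return A `grm` object (list: `values` n x n, `kind = "additive"`,
#'   `samples`, `denominator`).
#' @export
additive_grm <- function(designs) {
  stopifnot(inherits(designs, "design_pair"))
  denom <- sum(2 * designs$p * (1 - designs$p))
  if (denom <= 0) stop("all SNPs are monomorphic; additive GRM undefined")
  .grm_new(tcrossprod(designs$Z) / denom, "additive", designs$samples, denom)
}

#' Dominance genomic relationship matrix
#'
#' @param designs a `design_pair` from [build_designs()].
#' @return A `grm` object with `kind = "dominance"`.
#' @export
dominance_grm <- function(designs) {
  stopifnot(inherits(designs, "design_pair"))
  denom <- sum((2 * designs$p * (1 - designs$p))^2)
  if (all(designs$W == 0)) {
    # fully degenerate panel (every SNP monomorphic): no dominance
    # information at all; return the zero relationship rather than fail
    warning("dominance design is identically zero; dominance GRM is zero")
    n <- nrow(designs$W)
    return(.grm_new(matrix(0, n, n), "dominance", designs$samples, denom))
  }
  if (denom <= 0) stop("all SNPs are monomorphic; dominance GRM undefined")
  .grm_new(tcrossprod(designs$W) / denom, "dominance", designs$samples, denom)
}

#' @export
print.grm <- function(x, ...) {
  cat(x$kind, "GRM:", nrow(x$values), "samples, mean diagonal",
      round(mean(diag(x$values)), 4), "\n")
  invisible(x)
}

#' Write / read a GRM
#'
#' `write_grm` emits both the GCTA binary layout (`prefix.grm.bin`:
#' little-endian float32 lower triangle including the diagonal, row by row;
#' `prefix.grm.id`: FID/IID pairs; `prefix.grm.N.bin`: per-pair marker count)
#' and a plain TSV (`prefix.grm.tsv`). `read_grm` reads the binary layout
#' back.
#'
#' @param grm a `grm` object.
#' @param prefix output path prefix.
#' @param n_markers marker count written to `prefix.grm.N.bin`.
#' @return `prefix` (write) or a `grm` object (read), invisibly for write.
#' @export
write_grm <- function(grm, prefix, n_markers = NA_integer_) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  lower <- grm$values[lower.tri(grm$values, diag = TRUE)]
  # GCTA order is row-wise over the lower triangle: pair (i, j<=i) at position
  # i(i-1)/2 + j; lower.tri() extracts column-wise, so reorder
  idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower[ord]), con, size = 4, endian = "little")
  close(con)
  nm <- if (is.na(n_markers)) 0L else as.integer(n_markers)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(nm), n * (n + 1) / 2), con, size = 4, endian = "little")
  close(con)
  utils::write.table(data.frame(grm$samples, grm$samples),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- as.data.frame(grm$values)
  utils::write.table(cbind(id = grm$samples, tsv), paste0(prefix, ".grm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @param kind relationship kind recorded on the read-back object.
#' @param format `"bin"` (GCTA binary, default) or `"tsv"`.
#' @export
read_grm <- function(prefix, kind = "additive", format = c("bin", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(paste0(prefix, ".grm.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE)
    ids <- as.character(tab[[1]])
    G <- as.matrix(tab[, -1, drop = FALSE])
    return(.grm_new(unname(G), kind, ids, NA_real_))
  }
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  vals <- readBin(paste0(prefix, ".grm.bin"), what = "numeric", size = 4,
                  n = n * (n + 1) / 2, endian = "little")
  G <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    G[i, 1:i] <- vals[k:(k + i - 1L)]
    k <- k + i
  }
  G <- G + t(G) - diag(diag(G))
  .grm_new(G, kind, ids, NA_real_)
}
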