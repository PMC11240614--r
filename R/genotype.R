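#' Construct a genotype matrix object
#'
#' The central genotype container: an `n x m` matrix of biallelic calls in
#' `{0, 1, 2, NA}` counting copies of the counted allele, together with a SNP
#' map (id, chromosome, 1-based position, counted and other allele) and sample
#' identifiers. Every downstream stage (QC, imputation, design coding, kinship,
#' scans) consumes this object.
#'
#' @param calls integer or numeric matrix, samples in rows, SNPs in columns;
#'   values 0/1/2 or `NA` for missing.
#' @param map data.frame with columns `id`, `chr`, `pos`, `a1`, `a2`: one row
#'   per SNP. `a1` is the counted allele (the allele whose copies `calls`
#'   counts), `a2` the other allele. `pos` is 1-based.
#' @param samples character vector of sample identifiers, one per row of
#'   `calls`.
#' @return An object of class `genotype_matrix`: a list with elements `calls`
#'   (dimnames set to samples x SNP ids), `map`, `samples`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1, NA, 0), nrow = 3),
#'                      map = data.frame(id = c("s1", "s2"), chr = c("1", "1"),
#'                                       pos = c(100L, 200L),
#'                                       a1 = c("A", "G"), a2 = c("C", "T")),
#'                      samples = c("i1", "i2", "i3"))
#' dim(g)
#' @export
genotype_matrix <- function(calls, map, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(calls)))
  samples <- as.character(samples)
  stopifnot(is.data.frame(map))
  need <- c("id", "chr", "pos", "a1", "a2")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0) {
    stop("SNP map is missing column(s): ", paste(miss, collapse = ", "))
  }
  map <- as.data.frame(map)[, need]
  map$id <- as.character(map$id)
  map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  if (nrow(calls) != length(samples)) {
    stop("calls has ", nrow(calls), " rows but ", length(samples), " sample ids")
  }
  if (ncol(calls) != nrow(map)) {
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " SNPs")
  }
  ok <- calls %in% c(0, 1, 2) | is.na(calls)
  if (!all(ok)) {
    stop("genotype calls must be 0, 1, 2 or NA; found: ",
         paste(utils::head(unique(calls[!ok])), collapse = ", "))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples, map$id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$calls))
  cat("genotype_matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs (", nmiss, " missing calls)\n", sep = "")
  cat("chromosomes: ", paste(unique(x$map$chr), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (logical, integer or character).
#' @param j SNP index (logical, integer or character).
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the selected samples/SNPs.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$map))
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  map = x$map[j, , drop = FALSE],
                  samples = x$samples[i])
}

#' Counted-allele frequencies
#'
#' Per-SNP frequency of the counted allele, `p_j = sum(calls_j) / (2n)`.
#' Requires a complete (imputed) panel: the same frequencies are reused for
#' design centering and the kinship denominators, so they must come from one
#' well-defined sample.
#'
#' @param g a `genotype_matrix` with no missing calls.
#' @return Numeric vector of length `m` with values in `[0, 1]`, named by SNP id.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$calls)) {
    stop("panel contains missing calls; run impute_missing() before computing ",
         "allele frequencies")
  }
  colMeans(g$calls) / 2
}

#' Quality-control filter for a genotype panel
#'
#' Two-phase marker QC mirroring a standard array-data pipeline:
#' phase `"pre"` (before imputation) drops non-autosomal SNPs and SNPs with
#' call rate strictly below `call_rate_min`; phase `"post"` (after imputation)
#' drops SNPs with minor allele frequency strictly below `maf_min`. The MAF is
#' folded: `min(p, 1 - p)` of the counted allele. Phase `"both"` runs pre, then
#' (only valid on complete panels) post.
#'
#' @param g a `genotype_matrix`.
#' @param call_rate_min minimum call rate retained (SNPs with call rate
#'   `< call_rate_min` are removed; a SNP at exactly the threshold is kept).
#' @param maf_min minimum minor-allele frequency retained (strict `<` removal).
#' @param autosomes_only drop SNPs whose chromosome label is not in
#'   `autosomes`.
#' @param autosomes chromosome labels considered autosomal; defaults to
#'   `"1"`--`"18"`, the pig autosomes.
#' @param phase which QC phase to run; MAF filtering is defined on an imputed
#'   panel, so `"post"`/`"both"` require no missing calls.
#' @return A list with `genotypes` (the filtered `genotype_matrix`) and
#'   `report` (a `qc_report`: per-step removal tallies and thresholds).
#' @export
qc_filter <- function(g, call_rate_min = 0.95, maf_min = 0.01,
                      autosomes_only = TRUE,
                      autosomes = as.character(1:18),
                      phase = c("pre", "post", "both")) {
  stopifnot(inherits(g, "genotype_matrix"))
  phase <- match.arg(phase)
  n_input <- ncol(g$calls)
  if (n_input == 0) stop("empty genotype panel")
  n_nonauto <- 0L
  n_callrate <- 0L
  n_maf <- 0L

  if (phase %in% c("pre", "both")) {
    if (autosomes_only) {
      keep <- g$map$chr %in% autosomes
      n_nonauto <- sum(!keep)
      if (!all(keep)) g <- g[, keep]
    }
    if (ncol(g$calls) > 0) {
      cr <- colMeans(!is.na(g$calls))
      keep <- cr >= call_rate_min   # strict "<" removal rule
      n_callrate <- sum(!keep)
      if (!all(keep)) g <- g[, keep]
    }
  }
  if (phase %in% c("post", "both")) {
    if (anyNA(g$calls)) {
      stop("MAF filtering (phase \"post\") requires an imputed panel; ",
           "run impute_missing() first")
    }
    if (ncol(g$calls) > 0) {
      p <- allele_frequencies(g)
      maf <- pmin(p, 1 - p)
      keep <- maf >= maf_min
      n_maf <- sum(!keep)
      if (!all(keep)) g <- g[, keep]
    }
  }
  n_ret <- ncol(g$calls)
  if (n_ret == 0) {
    stop("QC removed every SNP in the panel (", n_input, " input); ",
         "check thresholds and chromosome labels")
  }
  report <- structure(list(
    n_input_snps = n_input,
    n_removed_nonautosomal = n_nonauto,
    n_removed_callrate = n_callrate,
    n_removed_maf = n_maf,
    n_retained = n_ret,
    thresholds = list(call_rate_min = call_rate_min, maf_min = maf_min,
                      autosomes_only = autosomes_only, phase = phase)
  ), class = "qc_report")
  stopifnot(n_input - (n_nonauto + n_callrate + n_maf) == n_ret)
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control (phase: ", x$thresholds$phase, ")\n", sep = "")
  cat("  input SNPs:          ", x$n_input_snps, "\n")
  cat("  removed non-autosomal:", x$n_removed_nonautosomal, "\n")
  cat("  removed call rate <", x$thresholds$call_rate_min, ":",
      x$n_removed_callrate, "\n")
  cat("  removed MAF <", x$thresholds$maf_min, ":", x$n_removed_maf, "\n")
  cat("  retained:            ", x$n_retained, "\n")
  invisible(x)
}

#' Write a QC report as a tab-separated summary
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  df <- data.frame(
    step = c("input", "nonautosomal", "callrate", "maf", "retained"),
    n = c(report$n_input_snps, report$n_removed_nonautosomal,
          report$n_removed_callrate, report$n_removed_maf, report$n_retained)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing genotype calls
#'
#' Simple single-marker imputation: `"mode"` replaces missing calls with the
#' SNP's most frequent observed genotype (ties broken toward the smaller
#' code); `"frequency_draw"` samples each missing call from the SNP's observed
#' genotype frequencies, reproducibly under `seed`.
#'
#' @param g a `genotype_matrix`.
#' @param method `"mode"` or `"frequency_draw"`.
#' @param seed integer seed used by `"frequency_draw"`.
#' @return A `genotype_matrix` with no missing calls.
#' @export
impute_missing <- function(g, method = c("mode", "frequency_draw"), seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  calls <- g$calls
  miss_col <- which(colSums(is.na(calls)) > 0)
  if (length(miss_col) == 0) return(g)
  zero_obs <- colSums(!is.na(calls)) == 0
  if (any(zero_obs)) {
    stop("cannot impute SNP(s) with zero observed calls: ",
         paste(utils::head(g$map$id[zero_obs]), collapse = ", "))
  }
  if (method == "frequency_draw") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  for (j in miss_col) {
    x <- calls[, j]
    obs <- x[!is.na(x)]
    counts <- tabulate(obs + 1L, nbins = 3L)  # genotypes 0,1,2
    if (method == "mode") {
      fill <- which.max(counts) - 1L          # which.max ties -> smaller code
      calls[is.na(x), j] <- fill
    } else {
      k <- sum(is.na(x))
      calls[is.na(x), j] <- sample(0:2, k, replace = TRUE, prob = counts / sum(counts))
    }
  }
  genotype_matrix(calls, map = g$map, samples = g$samples)
}

#' Build centered additive and dominance design matrices
#'
#' The additive coding counts copies of the counted allele (0/1/2) and is
#' centered by its mean `2p`; the dominance coding indicates heterozygosity
#' (0/1/0) and is centered by the expected heterozygosity under
#' Hardy-Weinberg, `2p(1-p)`. Columns are centered but not variance-scaled:
#' the kinship denominators `sum(2p(1-p))` and `sum([2p(1-p)]^2)` carry the
#' scale (VanRaden method-1 convention), so scaling here would
#' double-normalize. Dominance columns therefore have exactly zero mean only
#' when the sample heterozygosity matches its Hardy-Weinberg expectation.
#'
#' @param g an imputed, QC'd `genotype_matrix`.
#' @param p optional counted-allele frequencies; defaults to frequencies
#'   estimated from `g` itself.
#' @return A `design_pair`: list with `Z` (n x m centered additive), `W`
#'   (n x m centered dominance), `p` (frequencies used), `samples`, `map`.
#'   Monomorphic SNPs (p = 0 or 1) yield all-zero columns with a warning.
#' @export
build_designs <- function(g, p = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$calls)) stop("designs require an imputed panel; run impute_missing()")
  if (is.null(p)) p <- allele_frequencies(g)
  stopifnot(length(p) == ncol(g$calls), all(p >= 0 & p <= 1))
  mono <- p == 0 | p == 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) contribute all-zero design columns")
  }
  M <- g$calls
  storage.mode(M) <- "double"
  Z <- sweep(M, 2, 2 * p)
  H <- matrix(as.double(M == 1), nrow(M), ncol(M), dimnames = dimnames(M))
  W <- sweep(H, 2, 2 * p * (1 - p))
  # monomorphic columns: coding is constant, force exact zeros
  if (any(mono)) {
    Z[, mono] <- 0
    W[, mono] <- 0
  }
  structure(list(Z = Z, W = W, p = p, samples = g$samples, map = g$map),
            class = "design_pair")
}

#' @export
print.design_pair <- function(x, ...) {
  cat("design_pair: ", nrow(x$Z), " samples x ", ncol(x$Z), " SNPs\n", sep = "")
  cat("mean counted-allele frequency: ", round(mean(x$p), 4), "\n", sep = "")
  invisible(x)
}
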