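# Mixed-model association scans. The variance structure is
# y ~ N(Xb, sigma2_g * G + sigma2_e * I) with G the GRM matching the tested
# coding; after rotation into G's eigenbasis the model is a weighted
# regression, so the null variance ratio is profiled once (P3D) and every SNP
# column is tested by weighted least squares with a t/F Wald test on the
# marker coefficient.

# Null-model REML profile of delta = sigma2_e / sigma2_g in the rotated model.
# Returns delta, sigma2_g, sigma2_e and the rotation.
.null_mixed <- function(y, X, G, eig = NULL) {
  n <- length(y)
  if (is.null(eig)) eig <- eigen(G, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- ncol(X)
  restll <- function(logdelta) {
    d <- exp(logdelta)
    w <- lam + d
    Xw <- Xs / sqrt(w)
    yw <- ys / sqrt(w)
    A <- crossprod(Xw)
    bt <- solve(A, crossprod(Xw, yw))
    rss <- sum((yw - Xw %*% bt)^2)
    -0.5 * ((n - p) * log(rss) + sum(log(w)) + determinant(A)$modulus[1])
  }
  opt <- stats::optimize(restll, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8)
  d <- exp(opt$maximum)
  w <- lam + d
  Xw <- Xs / sqrt(w)
  yw <- ys / sqrt(w)
  bt <- solve(crossprod(Xw), crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% bt)^2)
  s2g <- rss / (n - p)
  list(delta = d, sigma2_g = s2g, sigma2_e = s2g * d,
       h2_pseudo = 1 / (1 + d / mean(lam[lam > 0])),
       U = U, lambda = lam, ys = ys)
}

# Weighted per-marker tests given the rotated pieces. Returns beta, se, p.
.marker_tests <- function(ys, Xs, Ss, w, n) {
  p <- ncol(Xs)
  sw <- sqrt(w)
  Xw <- Xs / sw
  yw <- ys / sw
  Sw <- Ss / sw
  A <- crossprod(Xw)
  Ai <- solve(A)
  cvec <- crossprod(Xw, yw)
  Aic <- drop(Ai %*% cvec)
  yPy <- sum(yw^2) - sum(cvec * Aic)
  B <- crossprod(Xw, Sw)                  # p x m
  AiB <- Ai %*% B
  sPs <- colSums(Sw^2) - colSums(B * AiB)
  sPy <- colSums(Sw * yw) - colSums(B * Aic)
  df <- n - p - 1
  bad <- sPs <= 1e-10 * colSums(Sw^2) | sPs <= 0
  beta <- sPy / sPs
  rss <- pmax(yPy - sPy^2 / sPs, 0)
  se <- sqrt(rss / df / sPs)
  # Wald test: marker z-score against the standard normal, residual variance
  # re-estimated per marker with the usual degrees-of-freedom correction
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  pval[pval == 0] <- .Machine$double.xmin  # keep p in (0, 1]
  beta[bad] <- NA_real_
  se[bad] <- NA_real_
  pval[bad] <- NA_real_
  if (any(bad)) {
    warning(sum(bad), " SNP(s) collinear with the fixed effects; ",
            "p-values set to NA")
  }
  list(beta = beta, se = se, p = pval)
}

.scan_frame <- function(designs, coding, tests, engine, response_label,
                        null_fit) {
  out <- data.frame(
    snp = designs$map$id, chr = designs$map$chr, pos = designs$map$pos,
    coding = coding, beta = tests$beta, se = tests$se, p = tests$p
  )
  attr(out, "engine") <- engine
  attr(out, "response") <- response_label
  attr(out, "delta") <- null_fit$delta
  attr(out, "h2_pseudo") <- null_fit$h2_pseudo
  class(out) <- c("scan_result", class(out))
  out
}

#' Single-locus mixed-model association scan
#'
#' EMMAX-style scan: the ratio `sigma2_e / sigma2_g` is profiled by REML on
#' the null model once (P3D, "population parameters previously determined"),
#' then every SNP column of the requested coding (centered additive `Z` or
#' centered dominance `W`) is tested by generalized least squares with a Wald
#' test on the marker coefficient, with the marker-model residual variance
#' re-estimated per marker. With `p3d = FALSE` the variance ratio is
#' re-profiled for every SNP (slow; retained as the exact reference).
#'
#' @param response numeric response vector (a trait, an adjusted trait, or a
#'   partial genetic value).
#' @param designs a `design_pair` from [build_designs()].
#' @param grm a `grm` for the variance structure; conventionally the additive
#'   GRM for additive-coded scans and the dominance GRM for dominance-coded
#'   scans.
#' @param coding `"additive"` (tests `Z` columns) or `"dominance"` (tests `W`
#'   columns).
#' @param X fixed-effects design matrix; default intercept-only.
#' @param p3d estimate variance components once on the null model (default)
#'   or per SNP.
#' @param response_label label stored on the result.
#' @return A `scan_result` data.frame (snp, chr, pos, coding, beta, se, p)
#'   with attributes `engine`, `response`, `delta`, `h2_pseudo`. SNP columns
#'   collinear with `X` get `NA` p-values with a warning.
#' @export
scan_single_locus <- function(response, designs, grm,
                              coding = c("additive", "dominance"),
                              X = NULL, p3d = TRUE,
                              response_label = "response") {
  coding <- match.arg(coding)
  stopifnot(inherits(designs, "design_pair"))
  y <- as.numeric(response)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  S <- if (coding == "additive") designs$Z else designs$W
  stopifnot(nrow(S) == n)
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  nf <- .null_mixed(y, X, G)
  if (p3d) {
    Ss <- crossprod(nf$U, S)
    tests <- .marker_tests(nf$ys, crossprod(nf$U, X), Ss, nf$lambda + nf$delta, n)
  } else {
    m <- ncol(S)
    beta <- se <- pv <- rep(NA_real_, m)
    Xs <- crossprod(nf$U, X)
    Ss <- crossprod(nf$U, S)
    for (j in seq_len(m)) {
      nj <- .null_mixed(y, cbind(X, S[, j]), G, eig = list(values = nf$lambda,
                                                           vectors = nf$U))
      tj <- .marker_tests(nf$ys, Xs, Ss[, j, drop = FALSE],
                          nf$lambda + nj$delta, n)
      beta[j] <- tj$beta
      se[j] <- tj$se
      pv[j] <- tj$p
    }
    tests <- list(beta = beta, se = se, p = pv)
  }
  .scan_frame(designs, coding, tests, "mlm", response_label, nf)
}

#' Stepwise multi-locus mixed-model scan
#'
#' Forward-inclusion multi-locus scan in the spirit of MLMM: at each step the
#' most significant SNP is promoted to a fixed-effect cofactor, the variance
#' ratio is re-profiled, and the loop stops when the pseudo-heritability of
#' the null model drops below `h2_stop` or `max_cofactors` is reached. Among
#' the visited models, the one minimizing the extended BIC
#' `n log(RSS/n) + k (log n + 2 gamma log m)` is selected, and the reported
#' p-values come from the selected model (each cofactor is tested against the
#' other cofactors; every other SNP is tested with the full selected cofactor
#' set in the design).
#'
#' @inheritParams scan_single_locus
#' @param max_cofactors cap on forward-selected cofactors; `0` reduces the
#'   scan to [scan_single_locus()].
#' @param h2_stop stop threshold on the null pseudo-heritability.
#' @param ebic_gamma extended-BIC genome-size weight.
#' @return A `scan_result` data.frame; attribute `cofactors` lists the
#'   selected SNP ids and `ebic` the per-model criterion trace.
#' @export
scan_multi_locus <- function(response, designs, grm,
                             coding = c("additive", "dominance"),
                             X = NULL, max_cofactors = 10, h2_stop = 0.01,
                             ebic_gamma = 1, response_label = "response") {
  coding <- match.arg(coding)
  stopifnot(inherits(designs, "design_pair"))
  y <- as.numeric(response)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  S <- if (coding == "additive") designs$Z else designs$W
  m <- ncol(S)
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  eig <- eigen(G, symmetric = TRUE)
  Ss_all <- crossprod(eig$vectors, S)

  ebic_of <- function(nf, k, Xk) {
    # ML deviance in the rotated model; the sum(log w) term keeps models
    # with different variance ratios comparable
    w <- nf$lambda + nf$delta
    Xw <- crossprod(eig$vectors, Xk) / sqrt(w)
    yw <- nf$ys / sqrt(w)
    rss <- sum(stats::lm.fit(Xw, yw)$residuals^2)
    dev <- n * log(rss / n) + sum(log(w))
    dev + k * (log(n) + 2 * ebic_gamma * log(m))
  }

  cof <- integer(0)
  visited <- list()
  repeat {
    Xk <- cbind(X, S[, cof, drop = FALSE])
    nf <- .null_mixed(y, Xk, G, eig = eig)
    free <- setdiff(seq_len(m), cof)
    tests <- .marker_tests(nf$ys, crossprod(eig$vectors, Xk),
                           Ss_all[, free, drop = FALSE],
                           nf$lambda + nf$delta, n)
    visited[[length(visited) + 1]] <- list(
      cofactors = cof, ebic = ebic_of(nf, length(cof), Xk),
      h2 = nf$h2_pseudo
    )
    if (length(cof) >= max_cofactors || nf$h2_pseudo < h2_stop) break
    best <- free[which.min(tests$p)]
    if (length(best) == 0 || all(is.na(tests$p))) break
    cof <- c(cof, best)
  }

  ebics <- vapply(visited, `[[`, numeric(1), "ebic")
  sel <- visited[[which.min(ebics)]]$cofactors

  # reported p-values from the selected model
  Xsel <- cbind(X, S[, sel, drop = FALSE])
  nf <- .null_mixed(y, Xsel, G, eig = eig)
  w <- nf$lambda + nf$delta
  beta <- se <- pv <- rep(NA_real_, m)
  free <- setdiff(seq_len(m), sel)
  t_free <- .marker_tests(nf$ys, crossprod(eig$vectors, Xsel),
                          Ss_all[, free, drop = FALSE], w, n)
  beta[free] <- t_free$beta
  se[free] <- t_free$se
  pv[free] <- t_free$p
  for (j in sel) {
    others <- setdiff(sel, j)
    Xo <- cbind(X, S[, others, drop = FALSE])
    t_j <- .marker_tests(nf$ys, crossprod(eig$vectors, Xo),
                         Ss_all[, j, drop = FALSE], w, n)
    beta[j] <- t_j$beta
    se[j] <- t_j$se
    pv[j] <- t_j$p
  }
  out <- .scan_frame(designs, coding, list(beta = beta, se = se, p = pv),
                     "mlmm", response_label, nf)
  attr(out, "cofactors") <- designs$map$id[sel]
  attr(out, "ebic") <- ebics
  out
}

#' Bonferroni significance thresholds
#'
#' Genome-wide significant (`0.05 / N`) and suggestive (`1 / N`) p-value
#' thresholds over `N` tested SNPs; their ratio is exactly 20.
#'
#' @param n_tests number of tests (SNPs).
#' @return A `thresholds` object: list with `n_tests`, `significant`,
#'   `suggestive`.
#' @examples
#' bonferroni_thresholds(112643)
#' @export
bonferroni_thresholds <- function(n_tests) {
  if (length(n_tests) != 1 || n_tests < 1) stop("n_tests must be >= 1")
  structure(list(n_tests = as.integer(n_tests),
                 significant = 0.05 / n_tests,
                 suggestive = 1 / n_tests),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("Bonferroni thresholds over %d tests: significant %.4g, suggestive %.4g\n",
              x$n_tests, x$significant, x$suggestive))
  invisible(x)
}

#' Combine scans from several engines into an ensemble
#'
#' A SNP enters the ensemble when at least `min_support` engines call it
#' below the chosen threshold tier. The output mirrors a per-trait results
#' table: SNP coordinates, the supporting engine list, the best p-value, and
#' the tier reached (`"significant"` if the support rule also holds at the
#' significant threshold).
#'
#' @param scans named list of `scan_result` objects over the same SNP panel
#'   and response.
#' @param thresholds a [bonferroni_thresholds()] object.
#' @param min_support minimum number of supporting engines.
#' @param tier `"suggestive"` or `"significant"`: threshold the support rule
#'   is applied at.
#' @return An `ensemble_result` data.frame: snp, chr, pos, n_support,
#'   engines (comma-separated), best_p, tier.
#' @export
ensemble_combine <- function(scans, thresholds, min_support = 2,
                             tier = c("suggestive", "significant")) {
  tier <- match.arg(tier)
  if (length(scans) == 0) stop("empty scan list")
  if (is.null(names(scans)) || any(names(scans) == "")) {
    names(scans) <- vapply(scans, function(s) attr(s, "engine"), character(1))
  }
  ref <- scans[[1]]$snp
  for (s in scans) {
    if (!identical(s$snp, ref)) stop("scans cover different SNP panels")
  }
  thr <- thresholds[[tier]]
  pmat <- vapply(scans, function(s) s$p, numeric(length(ref)))
  pmat <- matrix(pmat, nrow = length(ref))
  pass <- !is.na(pmat) & pmat < thr
  nsup <- rowSums(pass)
  keep <- which(nsup >= min_support)
  pass_sig <- !is.na(pmat) & pmat < thresholds$significant
  out <- data.frame(
    snp = ref[keep],
    chr = scans[[1]]$chr[keep],
    pos = scans[[1]]$pos[keep],
    n_support = nsup[keep],
    engines = vapply(keep, function(i) {
      paste(names(scans)[pass[i, ]], collapse = ",")
    }, character(1)),
    best_p = apply(pmat[keep, , drop = FALSE], 1, min, na.rm = TRUE),
    tier = ifelse(rowSums(pass_sig[keep, , drop = FALSE]) >= min_support,
                  "significant", "suggestive")
  )
  attr(out, "min_support") <- min_support
  attr(out, "tier_rule") <- tier
  class(out) <- c("ensemble_result", class(out))
  out
}
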