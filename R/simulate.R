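# Seeded generators for genotypes, F1 crosses and QTN phenotypes. These are
# first-class, tested code: they define the conditions under which the model
# and the scan engines are validated, so their defaults are the study design
# they emulate (6 sires x 24 dams -> 171 F1; 20 QTNs, N(0,1) effects,
# h^2 = 0.5).

#' Simulate a biallelic SNP panel
#'
#' Allele frequencies are drawn uniformly from `maf_range`; genotypes are
#' `Binomial(2, p)` per individual (Hardy-Weinberg). With `ld_decay > 0`,
#' genotypes are derived by thresholding an AR(1)-correlated latent Gaussian
#' across adjacent SNPs, inducing local LD with lag-1 genotype correlation
#' close to `ld_decay`.
#'
#' @param n_individuals,n_snps panel dimensions.
#' @param maf_range range the minor-allele frequency is drawn from; the
#'   counted allele is the minor or the major allele with equal probability,
#'   as on a genotyping array.
#' @param ld_decay AR(1) parameter in `[0, 1)` for adjacent-SNP latent
#'   correlation; 0 gives independent SNPs.
#' @param missing_rate fraction of calls set missing at random (default 0:
#'   complete panel).
#' @param n_chromosomes SNPs are split evenly over this many autosome labels,
#'   with positions spaced `spacing_bp` apart.
#' @param spacing_bp distance between adjacent simulated SNPs (bp).
#' @param seed integer seed; identical seeds give identical panels.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5),
                               ld_decay = 0, missing_rate = 0,
                               n_chromosomes = 18, spacing_bp = 10000L,
                               seed = 1L) {
  stopifnot(n_individuals > 0, n_snps > 0, ld_decay >= 0, ld_decay < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  # the counted allele of an array SNP is arbitrary: make it the minor or the
  # major allele with equal probability
  flip <- stats::runif(n_snps) < 0.5
  p[flip] <- 1 - p[flip]
  if (ld_decay == 0) {
    calls <- matrix(stats::rbinom(n_individuals * n_snps, 2L,
                                  rep(p, each = n_individuals)),
                    n_individuals, n_snps)
  } else {
    # two latent AR(1) gaussian haplotype streams, thresholded at qnorm(p)
    calls <- matrix(0L, n_individuals, n_snps)
    thr <- matrix(stats::qnorm(p), n_individuals, n_snps, byrow = TRUE)
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n_individuals * n_snps), n_individuals, n_snps)
      for (j in 2:n_snps) {
        z[, j] <- ld_decay * z[, j - 1] + sqrt(1 - ld_decay^2) * z[, j]
      }
      calls <- calls + (z < thr)
    }
    storage.mode(calls) <- "integer"
  }
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }
  chr <- sort(rep_len(seq_len(n_chromosomes), n_snps))  # contiguous blocks
  pos <- integer(n_snps)
  for (cc in unique(chr)) {
    k <- sum(chr == cc)
    pos[chr == cc] <- seq_len(k) * spacing_bp
  }
  map <- data.frame(id = sprintf("snp%05d", seq_len(n_snps)),
                    chr = as.character(chr), pos = pos,
                    a1 = "A", a2 = "B")
  genotype_matrix(calls, map = map,
                  samples = sprintf("ind%04d", seq_len(n_individuals)))
}

#' Simulate a QTN-architecture phenotype
#'
#' Draws `n_qtn` causal SNPs uniformly at random, gives each an effect from a
#' standard normal, and builds the genetic value from the additive (0/1/2) or
#' dominance (heterozygote indicator 0/1/0) coding of those SNPs. Residuals
#' are orthogonalized against the genetic value and rescaled so that the
#' realized `var(genetic) / var(phenotype)` equals `h2` exactly. Monomorphic
#' QTN draws are resampled (with a message) since they carry no signal.
#'
#' @param g an imputed [genotype_matrix()].
#' @param n_qtn number of causal SNPs.
#' @param h2 realized heritability of the simulated trait (broad-sense in
#'   dominance mode, where all genetic variance is dominance variance).
#' @param mode `"additive"` or `"dominance"` QTN gene action.
#' @param qtn_maf_min optional lower bound on QTN minor-allele frequency;
#'   `qtn_at` overrides random selection entirely.
#' @param qtn_at optional fixed QTN column indices.
#' @param seed integer seed.
#' @return A list with `y` (phenotype vector) and `truth` (a `sim_truth`:
#'   `qtn_index`, `qtn_id`, `effects`, `genetic_value`, `h2_realized`, `mode`).
#' @export
simulate_phenotype <- function(g, n_qtn = 20, h2 = 0.5,
                               mode = c("additive", "dominance"),
                               qtn_maf_min = 0, qtn_at = NULL, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), h2 > 0, h2 < 1,
            n_qtn <= ncol(g$calls))
  if (anyNA(g$calls)) stop("simulate_phenotype requires an imputed panel")
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p <- allele_frequencies(g)
  eligible <- which(p > 0 & p < 1 & pmin(p, 1 - p) >= qtn_maf_min)
  if (is.null(qtn_at)) {
    qtn <- sample(eligible, n_qtn)
    # a QTN that turned monomorphic carries no signal: resample
    tries <- 0L
    while (any(p[qtn] %in% c(0, 1)) && tries < 20L) {
      bad <- p[qtn] %in% c(0, 1)
      message("resampling ", sum(bad), " monomorphic QTN draw(s)")
      qtn[bad] <- sample(setdiff(eligible, qtn), sum(bad))
      tries <- tries + 1L
    }
  } else {
    qtn <- as.integer(qtn_at)
    n_qtn <- length(qtn)
  }
  effects <- stats::rnorm(n_qtn)
  M <- g$calls[, qtn, drop = FALSE]
  storage.mode(M) <- "double"
  coding <- if (mode == "additive") M else (M == 1) * 1.0
  gv <- drop(coding %*% effects)
  var_g <- stats::var(gv)
  if (var_g == 0) stop("simulated genetic value has zero variance")
  e <- stats::rnorm(length(gv))
  e <- stats::residuals(stats::lm(e ~ gv))        # exactly orthogonal to gv
  e <- e * sqrt(var_g * (1 - h2) / h2 / stats::var(e))
  y <- gv + e
  truth <- structure(list(qtn_index = qtn, qtn_id = g$map$id[qtn],
                          effects = effects, genetic_value = gv,
                          h2_realized = var_g / stats::var(y), mode = mode),
                     class = "sim_truth")
  list(y = y, truth = truth)
}

#' Simulate an F1 cross between two diverged parental pools
#'
#' Two parental pools (sire breed, dam breed) diverge from a common ancestral
#' frequency by a Balding-Nichols drift of strength `divergence` (an
#' Fst-like parameter). Each offspring receives one gamete from its sire and
#' one from its dam, gametes drawn per-locus from the parent's genotype
#' (transmission 0, 1/2 or 1 by dosage). Trait loci carry additive effects
#' plus a positive dominance degree, so crossbred offspring — more
#' heterozygous than either pool — exceed the mid-parent mean in expectation,
#' generating true mid-parent heterosis by construction.
#'
#' @param n_sires,n_dams,n_offspring mating design; offspring are assigned
#'   round-robin to sires and to dams nested within sire.
#' @param n_snps number of SNPs.
#' @param divergence Balding-Nichols Fst-like divergence between the pools.
#' @param n_trait_loci,dominance_degree trait architecture used to produce
#'   parental and offspring phenotypes: per-locus additive effect `a = 1` and
#'   heterozygote effect `d = dominance_degree`; positive values generate
#'   positive heterosis. The default is complete dominance (`d = 1`) at 100
#'   loci — the classical directional-dominance architecture of heterosis.
#' @param trait_mean,trait_sd baseline mean and residual SD of the trait.
#' @param maf_range ancestral allele-frequency range.
#' @param seed integer seed.
#' @return A list with `genotypes` (a [genotype_matrix()] over sires, dams and
#'   offspring), `pedigree` (data.frame id/sire/dam/role), `phenotypes`
#'   (data.frame id/role/value), and `parental_means` (named vector: mean
#'   trait of pool 1 = sires, pool 2 = dams).
#' @export
simulate_f1_cross <- function(n_sires = 6, n_dams = 24, n_offspring = 171,
                              n_snps = 5000, divergence = 0.2,
                              n_trait_loci = 100, dominance_degree = 1,
                              trait_mean = 100, trait_sd = 1,
                              maf_range = c(0.1, 0.9), seed = 1L) {
  stopifnot(n_sires > 0, n_dams > 0, n_offspring > 0, divergence >= 0,
            divergence < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p_anc <- stats::runif(n_snps, maf_range[1], maf_range[2])
  drift <- function(p, f) {
    if (f == 0) return(p)
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  p1 <- drift(p_anc, divergence)   # sire pool
  p2 <- drift(p_anc, divergence)   # dam pool
  draw_pool <- function(nind, p) {
    matrix(stats::rbinom(nind * length(p), 2L, rep(p, each = nind)),
           nind, length(p))
  }
  sires <- draw_pool(n_sires, p1)
  dams <- draw_pool(n_dams, p2)
  sire_of <- rep_len(seq_len(n_sires), n_offspring)
  # dams nested within sire so paternal half-sib groups look like the design
  dams_per_sire <- split(seq_len(n_dams), rep_len(seq_len(n_sires), n_dams))
  dam_of <- integer(n_offspring)
  for (s in seq_len(n_sires)) {
    k <- which(sire_of == s)
    dam_of[k] <- rep_len(dams_per_sire[[s]], length(k))
  }
  gamete <- function(geno_rows) {
    # transmission probability of the counted allele: dosage / 2
    pr <- geno_rows / 2
    matrix(stats::rbinom(length(pr), 1L, pr), nrow(pr), ncol(pr))
  }
  off <- gamete(sires[sire_of, , drop = FALSE]) +
    gamete(dams[dam_of, , drop = FALSE])
  calls <- rbind(sires, dams, off)
  ids <- c(sprintf("sire%02d", seq_len(n_sires)),
           sprintf("dam%02d", seq_len(n_dams)),
           sprintf("f1_%04d", seq_len(n_offspring)))
  role <- c(rep("sire", n_sires), rep("dam", n_dams), rep("f1", n_offspring))
  map <- data.frame(id = sprintf("snp%05d", seq_len(n_snps)),
                    chr = as.character(rep_len(1:18, n_snps)[order(rep_len(1:18, n_snps))]),
                    pos = 0L, a1 = "A", a2 = "B")
  chr_tab <- table(map$chr)
  map$pos <- unlist(lapply(chr_tab[unique(map$chr)], seq_len), use.names = FALSE) * 10000L
  g <- genotype_matrix(calls, map = map, samples = ids)
  # trait: additive + dominance loci shared by all animals
  loci <- sample.int(n_snps, n_trait_loci)
  add <- calls[, loci, drop = FALSE] %*% rep(1, n_trait_loci)
  dom <- (calls[, loci, drop = FALSE] == 1) %*% rep(dominance_degree, n_trait_loci)
  value <- trait_mean + drop(add + dom) + stats::rnorm(length(ids), sd = trait_sd)
  phenotypes <- data.frame(id = ids, role = role, value = value)
  pedigree <- data.frame(
    id = ids,
    sire = c(rep(NA_character_, n_sires + n_dams), sprintf("sire%02d", sire_of)),
    dam = c(rep(NA_character_, n_sires + n_dams), sprintf("dam%02d", dam_of)),
    role = role
  )
  parental_means <- c(p1 = mean(value[role == "sire"]),
                      p2 = mean(value[role == "dam"]))
  list(genotypes = g, pedigree = pedigree, phenotypes = phenotypes,
       parental_means = parental_means)
}

#' Count true and false QTN detections
#'
#' A detected SNP counts as a true positive when it coincides with a simulated
#' QTN (`window_bp = 0`) or lies within `window_bp` of one on the same
#' chromosome.
#'
#' @param detected character vector of detected SNP ids (e.g. an ensemble's
#'   SNPs or one engine's significant SNPs).
#' @param truth a `sim_truth` from [simulate_phenotype()].
#' @param map the SNP map of the scanned panel (needed when `window_bp > 0`).
#' @param window_bp matching window around each QTN.
#' @return A list with `tp`, `fp`, `n_detected`, `n_qtn`, and the matched QTN
#'   ids.
#' @export
evaluate_detection <- function(detected, truth, map = NULL, window_bp = 0) {
  stopifnot(inherits(truth, "sim_truth"))
  detected <- unique(as.character(detected))
  if (window_bp == 0) {
    hit <- detected %in% truth$qtn_id
    matched <- intersect(detected, truth$qtn_id)
  } else {
    if (is.null(map)) stop("window_bp > 0 requires the SNP map")
    qi <- match(truth$qtn_id, map$id)
    di <- match(detected, map$id)
    hit <- logical(length(detected))
    matched_idx <- logical(length(qi))
    for (k in seq_along(di)) {
      same <- map$chr[qi] == map$chr[di[k]] &
        abs(map$pos[qi] - map$pos[di[k]]) <= window_bp
      hit[k] <- any(same)
      matched_idx <- matched_idx | same
    }
    matched <- truth$qtn_id[matched_idx]
  }
  # tp counts distinct true QTNs recovered (the replication study's metric);
  # fp counts detected SNPs matching no QTN
  list(tp = length(matched), fp = sum(!hit), n_detected = length(detected),
       n_qtn = length(truth$qtn_id), matched_qtn = matched)
}
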