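test_that("Bonferroni thresholds are exact divisions with ratio 20", {
  th <- bonferroni_thresholds(100)
  expect_equal(th$significant, 5e-4)
  expect_equal(th$suggestive, 1e-2)
  th2 <- bonferroni_thresholds(112643)
  expect_equal(th2$significant, 0.05 / 112643)
  expect_equal(round(th2$significant / 1e-7, 4), 4.4388)
  expect_equal(round(th2$suggestive / 1e-6, 4), 8.8776)
  for (N in c(1, 7, 5000)) {
    t0 <- bonferroni_thresholds(N)
    expect_equal(t0$suggestive / t0$significant, 20)
  }
  expect_error(bonferroni_thresholds(0), ">= 1")
})

test_that("P3D scan matches the dense-GLS oracle and OLS under identity kinship", {
  g <- simulate_genotypes(40, 50, seed = 9)
  d <- build_designs(g)
  Ga <- additive_grm(d)
  sim <- simulate_phenotype(g, n_qtn = 2, h2 = 0.4, seed = 3)
  X <- matrix(1, 40, 1)
  sc <- scan_single_locus(sim$y, d, Ga, "additive")
  # oracle: V at the scan's null estimates, explicit dense inverse
  delta <- attr(sc, "delta")
  V <- Ga$values + diag(delta, 40)
  p_or <- gls_oracle_p(sim$y, X, d$Z, V)
  expect_lt(max(abs(sc$p - p_or)), 1e-8)

  # identity kinship: p-values equal ordinary least-squares Wald p-values
  sc_id <- scan_single_locus(sim$y, d, diag(40), "additive")
  p_ols <- vapply(seq_len(50), function(j) {
    f <- stats::lm(sim$y ~ d$Z[, j])
    z <- stats::summary.lm(f)$coefficients[2, 3]
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  expect_lt(max(abs(sc_id$p - p_ols)), 1e-10)
})

test_that("per-SNP variance re-estimation (p3d = FALSE) stays close to P3D", {
  g <- simulate_genotypes(60, 30, seed = 21)
  d <- build_designs(g)
  Ga <- additive_grm(d)
  set.seed(4)
  y <- stats::rnorm(60)
  a <- scan_single_locus(y, d, Ga, "additive", p3d = TRUE)
  b <- scan_single_locus(y, d, Ga, "additive", p3d = FALSE)
  expect_equal(a$p, b$p, tolerance = 0.05)
  expect_identical(a$snp, b$snp)
})

test_that("single-locus scan is calibrated under the null and powered at a QTN", {
  g <- simulate_genotypes(500, 2000, seed = 63)
  d <- build_designs(g)
  Ga <- additive_grm(d)
  set.seed(64)
  y <- stats::rnorm(500)
  sc <- scan_single_locus(y, d, Ga, "additive")
  expect_identical(nrow(sc), 2000L)             # every SNP exactly once
  expect_true(all(sc$p > 0 & sc$p <= 1))
  expect_lt(stats::ks.test(sc$p, "punif")$statistic, 0.05)

  hits <- vapply(1:10, function(r) {
    gg <- simulate_genotypes(500, 400, seed = 700 + r)
    dd <- build_designs(gg)
    sim <- simulate_phenotype(gg, n_qtn = 1, h2 = 0.2, seed = 800 + r)
    s <- scan_single_locus(sim$y, dd, additive_grm(dd), "additive")
    s$snp[which.min(s$p)] == sim$truth$qtn_id
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("collinear SNP columns give NA p-values with a warning", {
  g <- simulate_genotypes(50, 10, seed = 2)
  d <- build_designs(g)
  d$Z[, 3] <- 0  # degenerate column
  set.seed(5)
  expect_warning(sc <- scan_single_locus(stats::rnorm(50), d, additive_grm(d),
                                         "additive"),
                 "collinear")
  expect_true(is.na(sc$p[3]))
  expect_identical(sum(is.na(sc$p)), 1L)
})

test_that("multi-locus scan with no cofactor budget reduces to single locus", {
  g <- simulate_genotypes(120, 150, seed = 14)
  d <- build_designs(g)
  Ga <- additive_grm(d)
  sim <- simulate_phenotype(g, n_qtn = 3, h2 = 0.4, seed = 15)
  s1 <- scan_single_locus(sim$y, d, Ga, "additive")
  s0 <- scan_multi_locus(sim$y, d, Ga, "additive", max_cofactors = 0)
  expect_equal(s0$p, s1$p, tolerance = 1e-10)
  expect_identical(attr(s0, "cofactors"), character(0))
})

test_that("stepwise scan promotes planted QTNs and stays empty under the null", {
  both <- vapply(1:6, function(r) {
    g <- simulate_genotypes(500, 600, seed = 900 + r)
    d <- build_designs(g)
    set.seed(950 + r)
    q <- sample(600, 2)
    M <- scale(matrix(as.double(g$calls[, q]), ncol = 2))
    gv <- drop(M %*% c(1, 1))
    y <- gv + stats::rnorm(500, sd = sqrt(2 / 0.3 - 2))  # 15% VE per QTN
    ml <- scan_multi_locus(y, d, additive_grm(d), "additive")
    length(intersect(attr(ml, "cofactors"), g$map$id[q])) == 2
  }, logical(1))
  expect_gte(mean(both), 0.8)

  nulls <- vapply(1:6, function(r) {
    g <- simulate_genotypes(400, 600, seed = 1000 + r)
    d <- build_designs(g)
    set.seed(1050 + r)
    ml <- scan_multi_locus(stats::rnorm(400), d, additive_grm(d), "additive")
    length(attr(ml, "cofactors"))
  }, numeric(1))
  expect_gte(mean(nulls == 0), 0.8)
})

test_that("additive PGVs recover planted QTNs at least as often as the raw trait", {
  res <- t(vapply(1:12, function(r) {
    g <- simulate_genotypes(300, 800, seed = 8000 + r)
    d <- build_designs(g)
    Ga <- additive_grm(d)
    Gd <- dominance_grm(d)
    sim <- simulate_phenotype(g, n_qtn = 5, h2 = 0.3, seed = 8500 + r)
    fit <- suppressMessages(fit_reml(sim$y, Ga, Gd))
    th <- bonferroni_thresholds(800)$significant
    sy <- scan_single_locus(sim$y, d, Ga, "additive")
    sp <- scan_single_locus(partial_genetic_values(fit)$ya, d, Ga, "additive")
    c(raw = evaluate_detection(sy$snp[sy$p < th], sim$truth)$tp,
      pgv = evaluate_detection(sp$snp[sp$p < th], sim$truth)$tp)
  }, numeric(2)))
  expect_gte(mean(res[, "pgv"]), mean(res[, "raw"]))
})

test_that("ensemble combination applies the support rule over shared panels", {
  mk_scan <- function(p, engine) {
    s <- data.frame(snp = paste0("s", 1:4), chr = "1", pos = 1:4 * 10,
                    coding = "additive", beta = 0, se = 1, p = p)
    attr(s, "engine") <- engine
    class(s) <- c("scan_result", class(s))
    s
  }
  th <- bonferroni_thresholds(100)  # suggestive 1e-2, significant 5e-4
  a <- mk_scan(c(1e-3, 1e-3, 0.5, 1e-5), "mlm")
  b <- mk_scan(c(5e-3, 0.2, 0.5, 1e-6), "mlmm")
  ens <- ensemble_combine(list(mlm = a, mlmm = b), th)
  expect_identical(ens$snp, c("s1", "s4"))      # s2: single support, excluded
  expect_identical(ens$engines, c("mlm,mlmm", "mlm,mlmm"))
  expect_identical(ens$tier, c("suggestive", "significant"))
  expect_equal(ens$best_p, c(1e-3, 1e-6))
  expect_error(ensemble_combine(list(), th), "empty")
  bad <- mk_scan(rep(0.5, 4), "x")
  bad$snp <- rev(bad$snp)
  expect_error(ensemble_combine(list(a, bad), th), "different SNP panels")
})

test_that("nearest-gene annotation: containment, sign and tie-break", {
  genes <- data.frame(gene = c("G1", "G2", "G3"), chr = c("1", "1", "2"),
                      start = c(1000, 5000, 100), end = c(2000, 6000, 200),
                      strand = c("+", "-", "+"))
  snps <- data.frame(id = c("in1", "up1", "down1", "far"),
                     chr = c("1", "1", "1", "3"),
                     pos = c(1500, 610, 2500, 50))
  expect_warning(ann <- annotate_nearest_gene(snps, genes), "absent")
  expect_equal(ann$distance[ann$snp == "in1"], 0)
  # gene [1000,2000], SNP at 610: gene at higher coordinates -> +390
  expect_equal(ann$distance[ann$snp == "up1"], 390)
  expect_identical(ann$gene[ann$snp == "up1"], "G1")
  # SNP past the gene end -> negative distance
  expect_equal(ann$distance[ann$snp == "down1"], -500)
  expect_true(is.na(ann$gene[ann$snp == "far"]))

  # equidistant genes: smaller start coordinate wins, with a message
  genes2 <- data.frame(gene = c("L", "R"), chr = "1",
                       start = c(100, 500), end = c(200, 600))
  snpm <- data.frame(id = "mid", chr = "1", pos = 350)
  expect_message(tie <- annotate_nearest_gene(snpm, genes2), "equidistant")
  expect_identical(tie$gene, "L")
  expect_equal(tie$distance, -150)  # L sits at lower coordinates
})

test_that("gene annotation reads from GFF3 through the standard importer", {
  skip_if_not_installed("rtracklayer")
  gff <- file.path(withr::local_tempdir(), "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gene:G1;Name=MAP9",
    "1\ttest\texon\t1000\t1200\t.\t+\t.\tID=exon:1",
    "2\ttest\tgene\t300\t900\t.\t-\t.\tID=gene:G2;Name=API5"
  ), gff)
  genes <- read_gene_annotation(gff)
  expect_identical(nrow(genes), 2L)  # exon dropped
  expect_identical(genes$gene, c("MAP9", "API5"))
  ann <- annotate_nearest_gene(
    data.frame(id = "s", chr = "1", pos = 610), genes)
  expect_equal(ann$distance, 390)
  expect_identical(ann$gene, "MAP9")
})

test_that("scan plots carry every tested SNP and return ggplot objects", {
  g <- simulate_genotypes(80, 120, seed = 33)
  d <- build_designs(g)
  sim <- simulate_phenotype(g, n_qtn = 2, h2 = 0.4, seed = 34)
  sc <- scan_single_locus(sim$y, d, additive_grm(d), "additive")
  mp <- manhattan_plot(sc, bonferroni_thresholds(120))
  qp <- qq_plot(sc)
  expect_s3_class(mp, "ggplot")
  expect_s3_class(qp, "ggplot")
  expect_identical(nrow(mp$data), 120L)
})
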