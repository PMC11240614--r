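test_that("genotype matrix validates shape and call values", {
  g <- tiny_panel()
  expect_identical(dim(g), c(3L, 2L))
  expect_identical(sum(is.na(g$calls)), 1L)
  expect_true(is.na(g$calls["i2", "rs2"]))
  expect_error(genotype_matrix(matrix(3L, 1, 1),
                               map = data.frame(id = "x", chr = "1", pos = 1,
                                                a1 = "A", a2 = "B"),
                               samples = "s"),
               "0, 1, 2 or NA")
  expect_error(genotype_matrix(matrix(0L, 2, 2), map = tiny_panel()$map,
                               samples = "only_one"),
               "sample ids")
})

test_that("PLINK round-trip reproduces calls, order and missingness exactly", {
  g <- tiny_panel()
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$samples, g$samples)
  expect_identical(g2$map$id, g$map$id)
  expect_identical(g2$map$pos, g$map$pos)

  # sizes that exercise every byte-packing remainder (n mod 4 = 0..3)
  for (n in 5:8) {
    gs <- simulate_genotypes(n, 13, missing_rate = 0.1, seed = n)
    ps <- file.path(withr::local_tempdir(), "p")
    write_plink(gs, ps)
    expect_identical(read_plink(ps)$calls, gs$calls)
  }
})

test_that("VCF coding table and PLINK/VCF representation equivalence hold", {
  skip_if_not_installed("vcfR")
  g <- tiny_panel()
  dirp <- withr::local_tempdir()
  vcf <- file.path(dirp, "panel.vcf")
  write_vcf(g, vcf)
  gv <- read_vcf(vcf)
  # GT 0/1 -> 1, ./. -> missing, and full identity with the PLINK encoding
  expect_identical(gv$calls["i2", "rs1"], 1L)
  expect_true(is.na(gv$calls["i2", "rs2"]))
  write_plink(g, file.path(dirp, "panel"))
  gp <- read_plink(file.path(dirp, "panel"))
  expect_identical(gv$calls, gp$calls)
  expect_identical(gv$map$chr, gp$map$chr)
})

test_that("multiallelic VCF records are skipped with a warning", {
  skip_if_not_installed("vcfR")
  dirp <- withr::local_tempdir()
  vcf <- file.path(dirp, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/1\t1|1",
    "1\t200\tv2\tA\tG,T\t.\t.\t.\tGT\t0/1\t0/2",
    "1\t300\tv3\tC\tT\t.\t.\t.\tGT\t./.\t0/0"
  ), vcf)
  expect_warning(g <- read_vcf(vcf), "multiallelic")
  expect_identical(dim(g), c(2L, 2L))
  expect_identical(unname(g$calls[, "v1"]), c(1L, 2L))
  expect_true(is.na(g$calls[1, "v3"]))
})

test_that("allele frequencies follow the allele-copy count", {
  g <- hand_panel()
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(0, 0.5, 5 / 8))
  expect_error(allele_frequencies(tiny_panel()), "impute")
})

test_that("QC filters apply in order with strict-< thresholds and tally", {
  # call rate boundary: 94/100 removed, exactly 95/100 kept
  calls <- matrix(0L, 100, 3)
  calls[sample(100, 6), 1] <- NA   # call rate 0.94 -> removed
  calls[sample(100, 5), 2] <- NA   # call rate 0.95 -> retained
  g <- genotype_matrix(calls,
                       map = data.frame(id = paste0("m", 1:3),
                                        chr = c("1", "1", "X"),
                                        pos = 1:3, a1 = "A", a2 = "B"))
  res <- qc_filter(g, phase = "pre")
  expect_identical(res$report$n_removed_nonautosomal, 1L)
  expect_identical(res$report$n_removed_callrate, 1L)
  expect_identical(res$genotypes$map$id, "m2")
  expect_identical(res$report$n_input_snps -
                     (res$report$n_removed_nonautosomal +
                        res$report$n_removed_callrate +
                        res$report$n_removed_maf),
                   res$report$n_retained)
})

test_that("MAF phase removes planted rare SNPs after imputation", {
  set.seed(42)
  g <- simulate_genotypes(100, 95, maf_range = c(0.1, 0.4), seed = 7)
  # plant 5 SNPs at MAF 0.005 (one het allele among 200)
  rare <- matrix(0L, 100, 5)
  rare[1, ] <- 1L
  calls <- cbind(g$calls, rare)
  map <- rbind(g$map,
               data.frame(id = paste0("rare", 1:5), chr = "1",
                          pos = 1:5 + 1e6, a1 = "A", a2 = "B"))
  gg <- genotype_matrix(calls, map = map, samples = g$samples)
  res <- qc_filter(gg, phase = "post")
  expect_identical(res$report$n_removed_maf, 5L)
  expect_identical(res$report$n_retained, 95L)

  # idempotence: a second pass removes nothing
  res2 <- qc_filter(res$genotypes, phase = "both")
  expect_identical(res2$report$n_removed_nonautosomal, 0L)
  expect_identical(res2$report$n_removed_callrate, 0L)
  expect_identical(res2$report$n_removed_maf, 0L)
  expect_identical(res2$genotypes$calls, res$genotypes$calls)

  expect_error(qc_filter(gg, maf_min = 0.999, phase = "post"), "every SNP")
})

test_that("imputation fills by mode with small-code ties and is seeded", {
  g1 <- genotype_matrix(matrix(c(0L, 0L, 1L, NA), 4),
                        map = data.frame(id = "a", chr = "1", pos = 1,
                                         a1 = "A", a2 = "B"))
  expect_identical(unname(impute_missing(g1, "mode")$calls[4, 1]), 0L)
  g2 <- genotype_matrix(matrix(c(0L, 1L, 1L, 2L, NA), 5),
                        map = g1$map)
  expect_identical(unname(impute_missing(g2, "mode")$calls[5, 1]), 1L)
  # tie 0 vs 1 -> smaller code
  g3 <- genotype_matrix(matrix(c(0L, 1L, NA), 3), map = g1$map)
  expect_identical(unname(impute_missing(g3, "mode")$calls[3, 1]), 0L)

  gm <- simulate_genotypes(50, 40, missing_rate = 0.2, seed = 2)
  a <- impute_missing(gm, "frequency_draw", seed = 99)
  b <- impute_missing(gm, "frequency_draw", seed = 99)
  expect_identical(a$calls, b$calls)
  expect_false(anyNA(a$calls))

  g0 <- genotype_matrix(matrix(NA_integer_, 3, 1), map = g1$map)
  expect_error(impute_missing(g0), "zero observed")
})

test_that("design coding: centering identities and monomorphic handling", {
  g <- hand_panel()[, 2:3]  # drop the monomorphic column
  d <- build_designs(g)
  # additive columns centered exactly
  expect_lt(max(abs(colSums(d$Z))), 1e-12)
  # heterozygote at p = 0.5: Z entry 0, W entry 0.5
  expect_equal(unname(d$Z[2, "m2"]), 0)
  expect_equal(unname(d$W[2, "m2"]), 0.5)
  # monomorphic SNP gives zero columns plus a warning
  expect_warning(dm <- build_designs(hand_panel()), "monomorphic")
  expect_true(all(dm$Z[, 1] == 0) && all(dm$W[, 1] == 0))
})

test_that("additive and dominance codings decorrelate on average under HWE", {
  g <- simulate_genotypes(2000, 500, seed = 31)
  d <- build_designs(g)
  cors <- vapply(seq_len(500), function(j) {
    stats::cor(d$Z[, j], d$W[, j])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})
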